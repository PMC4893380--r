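# Temporal feature tracking on the left camera's image plane.
#
# Pyramidal gradient-based (Lucas-Kanade) patch tracking against a fixed
# frame-0 template, with NCC verification: the track confidence at each frame
# is the NCC of the current patch against its template, and a feature whose
# confidence drops below the threshold is declared lost.  A per-frame
# displacement bound guards against teleporting onto similar texture.

#' Track features through an image sequence
#'
#' @param frames List of grayscale matrices (the left-camera sequence).
#' @param initial Feature tibble (from [detect_regions()]) or any data frame
#'   with `id`, `col`, `row` giving frame-1 positions.
#' @param patch_radius Template half-size (px).
#' @param pyramid_levels Number of pyramid levels.
#' @param confidence_threshold NCC below which a track is lost.
#' @param max_displacement Per-frame displacement bound (px).
#' @return Trajectory tibble: `id`, `frame`, `col`, `row`, `confidence`,
#'   `status` (`"tracked"` or `"lost"`).  Once lost, a track stays lost and
#'   keeps its last position.
#' @export
track_features <- function(frames, initial, patch_radius = 7,
                           pyramid_levels = 3, confidence_threshold = 0.7,
                           max_displacement = 20) {
  if (!length(frames)) {
    abort("empty frame sequence", class = "tissuedeform_invalid_input")
  }
  init <- as_tibble(initial)
  stopifnot(all(c("id", "col", "row") %in% names(init)))
  n <- nrow(init)
  nf <- length(frames)
  pyr0 <- build_pyramid(frames[[1]], pyramid_levels)
  templates <- lapply(seq_len(n), function(i) {
    lapply(seq_len(pyramid_levels), function(l) {
      sample_window(pyr0[[l]], init$col[i] / 2^(l - 1), init$row[i] / 2^(l - 1),
                    patch_radius)
    })
  })

  out <- vector("list", nf)
  out[[1]] <- tibble(id = init$id, frame = 1L, col = init$col, row = init$row,
                     confidence = 1, status = "tracked")
  col <- init$col; row <- init$row
  alive <- rep(TRUE, n)
  conf <- rep(1, n)

  for (f in seq_len(nf)[-1]) {
    pyr <- build_pyramid(frames[[f]], pyramid_levels)
    for (i in seq_len(n)) {
      if (!alive[i]) next
      c0 <- col[i]; r0 <- row[i]
      ci <- c0; ri <- r0
      ok <- TRUE
      for (l in rev(seq_len(pyramid_levels))) {
        s <- 2^(l - 1)
        res <- lk_align(pyr[[l]], templates[[i]][[l]], ci / s, ri / s,
                        patch_radius, max_shift = max_displacement / s + 2)
        if (is.null(res)) { ok <- FALSE; break }
        ci <- res$col * s; ri <- res$row * s
      }
      if (ok) {
        # affine refinement at the finest level: under local scale/shear
        # change a translation-only tracker lags systematically
        aff <- lk_align_affine(frames[[f]], templates[[i]][[1]], ci, ri,
                               patch_radius)
        if (!is.null(aff) && aff$ncc > 0) {
          cur <- sample_window(frames[[f]], ci, ri, patch_radius)
          if (aff$ncc >= ncc(cur, templates[[i]][[1]])) {
            ci <- aff$col; ri <- aff$row
            cf <- aff$ncc
          } else {
            cf <- ncc(cur, templates[[i]][[1]])
          }
        } else {
          cur <- sample_window(frames[[f]], ci, ri, patch_radius)
          cf <- ncc(cur, templates[[i]][[1]])
        }
      } else cf <- -1
      moved2 <- (ci - c0)^2 + (ri - r0)^2
      if (!ok || cf < confidence_threshold || moved2 > max_displacement^2) {
        alive[i] <- FALSE
        conf[i] <- max(cf, -1)
      } else {
        col[i] <- ci; row[i] <- ri; conf[i] <- cf
      }
    }
    out[[f]] <- tibble(id = init$id, frame = as.integer(f), col = col, row = row,
                       confidence = conf,
                       status = ifelse(alive, "tracked", "lost"))
  }
  dplyr::bind_rows(out)
}
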