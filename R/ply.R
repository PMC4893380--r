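# ASCII PLY point-cloud I/O (per-vertex x, y, z in mm, optional scalar
# properties such as "deformation").

#' Write a point cloud as ASCII PLY
#'
#' @param cloud Data frame with columns `x`, `y`, `z` (mm); any additional
#'   numeric columns named in `extra` are written as float vertex properties.
#' @param path Output path.
#' @param extra Character vector of extra numeric columns to include
#'   (by default, `deformation` if present).
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, extra = intersect("deformation", names(cloud))) {
  cloud <- as_tibble(cloud)
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  cols <- c("x", "y", "z", extra)
  header <- c(
    "ply", "format ascii 1.0",
    "comment generated by tissuedeform (units: mm)",
    paste("element vertex", nrow(cloud)),
    paste("property float", cols),
    "end_header"
  )
  body <- do.call(paste, lapply(cols, function(cn) sprintf("%.8g", cloud[[cn]])))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Minimal reader for files produced by [write_ply()] (single vertex element,
#' float properties).
#'
#' @param path Input path.
#' @return Tibble with one column per vertex property.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) abort("not an ASCII PLY file", class = "tissuedeform_invalid_ply")
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  body <- lines[end + seq_len(nv)]
  vals <- matrix(as.numeric(unlist(strsplit(body, "\\s+"))), ncol = length(props),
                 byrow = TRUE)
  colnames(vals) <- props
  as_tibble(as.data.frame(vals))
}
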