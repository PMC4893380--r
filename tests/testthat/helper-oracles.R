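# Exhaustive reference matcher: scores every admissible (i, j) pair directly
# from the constraint definition and applies the same deterministic
# tie-breaking; no shared selection code with match_global().
brute_force_match <- function(fL, fR, cfg = match_config()) {
  cand <- list()
  for (i in seq_len(nrow(fL))) {
    best <- NULL
    for (j in seq_len(nrow(fR))) {
      if (abs(fR$row[j] - fL$row[i]) > cfg$epipolar_tolerance) next
      disp <- fL$col[i] - fR$col[j]
      if (disp < cfg$min_disparity || disp > cfg$max_disparity) next
      A <- appearance_similarity(fL$patch[[i]], fR$patch[[j]])
      if (A <= cfg$thr_s) next
      e_i <- ellipse(c(fL$col[i], fL$row[i]), c(fL$s11[i], fL$s12[i], fL$s22[i]))
      e_j <- ellipse(c(fL$col[i], fL$row[i]), c(fR$s11[j], fR$s12[j], fR$s22[j]))
      iou <- ellipse_overlap(e_i, e_j)
      if (iou <= cfg$thr_r) next
      M <- iou + min(fL$c[i], fR$c[j]) / max(fL$c[i], fR$c[j])
      if (is.null(best) || M > best$M ||
          (M == best$M && (A > best$A || (A == best$A && disp < best$disp)))) {
        best <- list(j = j, M = M, A = A, disp = disp)
      }
    }
    if (!is.null(best)) {
      cand[[length(cand) + 1]] <- data.frame(
        left_id = fL$id[i], right_id = fR$id[best$j], M = best$M, A = best$A
      )
    }
  }
  out <- do.call(rbind, cand)
  if (is.null(out)) return(out)
  out <- out[order(-out$M, -out$A, out$left_id), ]
  out <- out[!duplicated(out$right_id), ]
  out[order(out$left_id), ]
}
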