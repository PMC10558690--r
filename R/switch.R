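#' Compare enrichment profiles between illumination conditions
#'
#' Computes per-site light-minus-dark deltas on combined scores, plus
#' replicate-wise deltas. Floored scores participate as-is: extinction under
#' one condition is precisely the signature of a strong switch. Deltas are
#' defined only where both conditions are non-missing.
#'
#' @param dark,light `enrichment_profile`s of the same protein and sites
#'   with equal replicate counts.
#' @return A `condition_comparison`: data.frame with columns site, dark,
#'   light, delta, one `delta_rep*` column per replicate, and `defined`.
#' @export
compare_conditions <- function(dark, light) {
  if (length(dark$site) != length(light$site) ||
      any(dark$site != light$site)) {
    it_stop("profiles cover different site ranges", "shape_error")
  }
  if (ncol(dark$rep_scores) != ncol(light$rep_scores)) {
    it_stop("profiles have different replicate counts", "shape_error")
  }
  defined <- !dark$missing & !light$missing
  delta <- ifelse(defined, light$combined - dark$combined, NA_real_)
  rep_delta <- light$rep_scores - dark$rep_scores
  rep_delta[!defined, ] <- NA_real_
  colnames(rep_delta) <- paste0("delta_rep", seq_len(ncol(rep_delta)))
  out <- data.frame(site = dark$site, dark = dark$combined,
                    light = light$combined, delta = delta, rep_delta,
                    defined = defined)
  class(out) <- c("condition_comparison", "data.frame")
  out
}

#' Call switch variants from a condition comparison
#'
#' A site is called `light_ON` when its combined delta is at least `+tau`
#' and every replicate delta is positive, `light_OFF` when the delta is at
#' most `-tau` and every replicate delta is negative, and `none` otherwise.
#' With two replicates per condition, this effect-size-plus-sign-consistency
#' rule replaces an underpowered formal test; raising `tau` never increases
#' the number of calls.
#'
#' @param comparison A `condition_comparison`.
#' @param tau Calling threshold in log2 units (default 2).
#' @return The comparison with `call` (none/light_ON/light_OFF) and
#'   `consistent` columns added.
#' @export
call_switches <- function(comparison, tau = 2) {
  repcols <- grep("^delta_rep", names(comparison), value = TRUE)
  rd <- as.matrix(comparison[repcols])
  all_pos <- rowSums(rd > 0) == ncol(rd)
  all_neg <- rowSums(rd < 0) == ncol(rd)
  call <- rep("none", nrow(comparison))
  on <- comparison$defined & comparison$delta >= tau & all_pos
  off <- comparison$defined & comparison$delta <= -tau & all_neg
  call[on] <- "light_ON"
  call[off] <- "light_OFF"
  comparison$call <- call
  comparison$consistent <- comparison$defined & (all_pos | all_neg)
  comparison
}

#' Write a condition comparison TSV
#'
#' Columns `site dark light delta call consistent` (plus replicate deltas) —
#' the tabular analogue of a light-vs-dark enrichment scatter plot.
#' @param x A `condition_comparison` (after [call_switches()]).
#' @param path Output path.
#' @export
write_comparison_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
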