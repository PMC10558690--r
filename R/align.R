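#' BLOSUM62 substitution matrix restricted to the standard alphabet
#' @return 20 x 20 numeric matrix over [AA_STANDARD].
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_STANDARD, AA_STANDARD]
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch-Gotoh global alignment. A gap run of length g scores
#' `gap_open + (g - 1) * gap_extend` (both penalties are non-positive
#' scores). Ties are broken deterministically: substitution is preferred
#' over a gap in the homolog row, which is preferred over a gap in the query
#' row. Only the resulting gap statistics feed downstream analyses, so any
#' fixed rule would do; this one is the package's convention.
#'
#' @param query,homolog Non-empty amino-acid strings over the substitution
#'   matrix's alphabet.
#' @param substitution_matrix Square scoring matrix with residue dimnames;
#'   default [blosum62()].
#' @param gap_open,gap_extend Gap penalties (scores, <= 0); defaults -11/-1.
#' @return A `pairwise_alignment`: list with `query`, `homolog`,
#'   `aligned_query`, `aligned_homolog` (gap character `-`), `score`, and
#'   `gap_runs` (data.frame: side = insertion/deletion, anchor, length,
#'   terminal). For an insertion run (gap in the query row) `anchor` is the
#'   insertion site, i.e. the number of query residues preceding the run;
#'   for a deletion run it is the first deleted query residue.
#' @export
align_pair <- function(query, homolog, substitution_matrix = blosum62(),
                       gap_open = -11, gap_extend = -1) {
  if (!nchar(query) || !nchar(homolog)) {
    it_stop("sequences must be non-empty", "invalid_input")
  }
  alpha <- rownames(substitution_matrix)
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  hc <- strsplit(homolog, "", fixed = TRUE)[[1]]
  qi <- match(qc, alpha)
  hi <- match(hc, alpha)
  if (anyNA(qi) || anyNA(hi)) {
    it_stop("sequence letters outside the substitution matrix alphabet",
            "invalid_input")
  }
  res <- .gotoh_align(qi - 1L, hi - 1L, substitution_matrix,
                      gap_open, gap_extend)
  aq <- ifelse(is.na(res$query_idx), "-", qc[res$query_idx])
  ah <- ifelse(is.na(res$homolog_idx), "-", hc[res$homolog_idx])
  out <- list(query = query, homolog = homolog,
              aligned_query = paste(aq, collapse = ""),
              aligned_homolog = paste(ah, collapse = ""),
              score = res$score,
              gap_runs = extract_gap_runs(res$query_idx, res$homolog_idx))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment (score %.1f)\n  %s\n  %s\n", x$score,
              x$aligned_query, x$aligned_homolog))
  invisible(x)
}

# gap runs from aligned index vectors (NA = gap)
extract_gap_runs <- function(query_idx, homolog_idx) {
  n <- length(query_idx)
  gap_q <- is.na(query_idx)   # insertion in homolog
  gap_h <- is.na(homolog_idx) # deletion of query residues
  runs <- function(mask, side) {
    r <- rle(mask)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(side = side, col_start = starts[keep], col_end = ends[keep],
               length = r$lengths[keep])
  }
  out <- rbind(runs(gap_q, "insertion"), runs(gap_h, "deletion"))
  if (is.null(out)) {
    return(data.frame(side = character(0), anchor = integer(0),
                      length = integer(0), terminal = logical(0)))
  }
  # anchor in query coordinates; count of query residues before the column
  q_before <- cumsum(!is.na(query_idx))
  anchor <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (out$side[i] == "insertion") {
      anchor[i] <- if (out$col_start[i] == 1L) 0L else
        q_before[out$col_start[i] - 1L]
    } else {
      anchor[i] <- query_idx[out$col_start[i]]
    }
  }
  terminal <- out$col_start == 1L | out$col_end == n
  data.frame(side = out$side, anchor = anchor, length = out$length,
             terminal = terminal, stringsAsFactors = FALSE)
}

#' Indel statistics from pairwise alignments against one query
#'
#' Position-wise insertion and deletion statistics over a set of homolog
#' alignments to the same query: the insertion frequency at site i (between
#' query residues i and i+1) is the fraction of homologs with at least one
#' internal insertion run anchored there; the deletion frequency at residue
#' i is the fraction of homologs aligning that residue to a gap; mean and
#' median insertion lengths at a site are taken over the homologs that
#' insert there (0 where none do, keeping the feature matrix dense).
#' Terminal gap runs are excluded: local-search homolog sets make terminal
#' gaps uninformative about insertion tolerance.
#'
#' @param alignments List of `pairwise_alignment`s sharing one query.
#' @return An `indel_stats` list: `sites` data.frame (site, insertion_freq,
#'   mean_ins_len, median_ins_len) over sites 1..L-1 and `residues`
#'   data.frame (residue, deletion_freq) over residues 1..L.
#' @export
indel_stats <- function(alignments) {
  if (!length(alignments)) it_stop("need >= 1 alignment", "invalid_input")
  queries <- unique(vapply(alignments, `[[`, character(1), "query"))
  if (length(queries) != 1L) {
    it_stop("alignments are against different queries", "invalid_input")
  }
  L <- nchar(queries)
  n <- length(alignments)
  ins_any <- matrix(FALSE, n, L - 1L)
  ins_len <- vector("list", L - 1L)
  del_any <- matrix(FALSE, n, L)
  for (h in seq_len(n)) {
    gr <- alignments[[h]]$gap_runs
    gr <- gr[!gr$terminal, , drop = FALSE]
    ins <- gr[gr$side == "insertion", , drop = FALSE]
    for (i in seq_len(nrow(ins))) {
      s <- ins$anchor[i]
      if (s >= 1L && s <= L - 1L && !ins_any[h, s]) {
        ins_any[h, s] <- TRUE
        ins_len[[s]] <- c(ins_len[[s]], ins$length[i])
      } else if (s >= 1L && s <= L - 1L) {
        # several runs at one site in one homolog: keep the first length
      }
    }
    del <- gr[gr$side == "deletion", , drop = FALSE]
    for (i in seq_len(nrow(del))) {
      pos <- del$anchor[i] + seq_len(del$length[i]) - 1L
      del_any[h, pos[pos <= L]] <- TRUE
    }
  }
  mean_len <- vapply(ins_len, function(v) if (length(v)) mean(v) else 0,
                     numeric(1))
  med_len <- vapply(ins_len, function(v) if (length(v)) median(v) else 0,
                    numeric(1))
  out <- list(
    sites = data.frame(site = seq_len(L - 1L),
                       insertion_freq = colMeans(ins_any),
                       mean_ins_len = mean_len,
                       median_ins_len = med_len),
    residues = data.frame(residue = seq_len(L),
                          deletion_freq = colMeans(del_any)))
  class(out) <- "indel_stats"
  out
}

#' Align a homolog set against a query
#'
#' @param query Query amino-acid string.
#' @param homologs [Biostrings::AAStringSet] or character vector.
#' @param ... Passed to [align_pair()].
#' @return List of `pairwise_alignment`s.
#' @export
align_homologs <- function(query, homologs, ...) {
  if (inherits(homologs, "AAStringSet")) homologs <- as.character(homologs)
  lapply(homologs, function(h) align_pair(query, h, ...))
}
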