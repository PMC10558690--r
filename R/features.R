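#' Query-anchored multiple sequence alignment
#'
#' An `msa` object stores, for each query position 1..L, the residues that
#' every row (query first, then homologs) aligns to that position;
#' homolog-specific insertion columns are dropped since positional
#' conservation only concerns query positions. `read_msa()` builds it from
#' an aligned FASTA (query row identified by name or taken as the first
#' record); `msa_from_alignments()` builds it from pairwise alignments
#' against the query.
#'
#' @param path Aligned FASTA file.
#' @param query_id Name of the query record; default the first record.
#' @return An `msa`: list with `query` (ungapped string) and `profile`
#'   (character matrix, rows = sequences, cols = query positions, gap `-`).
#' @export
read_msa <- function(path, query_id = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  if (!length(aln)) it_stop("empty alignment file", "parse_error")
  qi <- if (is.null(query_id)) 1L else match(query_id, names(aln))
  if (is.na(qi)) it_stop("query_id not found in alignment", "invalid_input")
  rows <- toupper(as.character(aln))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    it_stop("alignment rows have unequal widths", "parse_error")
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  qrow <- mat[qi, ]
  keep_cols <- qrow != "-"
  profile <- mat[c(qi, setdiff(seq_len(nrow(mat)), qi)), keep_cols,
                 drop = FALSE]
  x <- list(query = paste(qrow[keep_cols], collapse = ""), profile = profile)
  class(x) <- "msa"
  x
}

#' @rdname read_msa
#' @param alignments List of `pairwise_alignment`s sharing one query.
#' @export
msa_from_alignments <- function(alignments) {
  queries <- unique(vapply(alignments, `[[`, character(1), "query"))
  if (length(queries) != 1L) {
    it_stop("alignments are against different queries", "invalid_input")
  }
  L <- nchar(queries)
  prof <- matrix("-", nrow = length(alignments) + 1L, ncol = L)
  prof[1L, ] <- strsplit(queries, "", fixed = TRUE)[[1]]
  for (h in seq_along(alignments)) {
    a <- alignments[[h]]
    aq <- strsplit(a$aligned_query, "", fixed = TRUE)[[1]]
    ah <- strsplit(a$aligned_homolog, "", fixed = TRUE)[[1]]
    qpos <- cumsum(aq != "-")
    keep <- aq != "-"
    prof[h + 1L, qpos[keep]] <- ah[keep]
  }
  x <- list(query = queries, profile = prof)
  class(x) <- "msa"
  x
}

#' Amino-acid frequencies of an alignment column
#'
#' Frequencies over the non-gap residues of the column at a query position,
#' renormalized to sum to 1. Gaps and nonstandard letters are excluded; if
#' only the query residue occupies the column, its frequency is 1.
#'
#' @param msa An `msa`.
#' @param query_position Position in 1..L.
#' @return Named frequency vector over [AA_STANDARD] (sums to 1).
#' @export
column_frequencies <- function(msa, query_position) {
  L <- nchar(msa$query)
  if (query_position < 1L || query_position > L) {
    it_stop("query_position out of range", "invalid_input")
  }
  col <- msa$profile[, query_position]
  col <- col[col %in% AA_STANDARD]
  tab <- table(factor(col, levels = AA_STANDARD))
  if (sum(tab) == 0L) {
    it_stop("column contains no standard residues", "invalid_input")
  }
  setNames(as.numeric(tab) / sum(tab), AA_STANDARD)
}

#' Positional conservation as Kullback-Leibler divergence
#'
#' \deqn{Divergence_i = \sum_a f_i(a) \log_{10}( f_i(a) / b(a) )}
#' where `f` are the column's amino-acid frequencies and `b` the background
#' frequencies. Terms with `f(a) = 0` contribute nothing; the value is a true
#' (base-10 scaled) KLD, hence non-negative, and 0 iff `f = b`.
#'
#' @param freqs Frequency vector over [AA_STANDARD], summing to 1.
#' @param background Background frequencies (default [swissprot_background()]);
#'   must be strictly positive.
#' @return Divergence in log10 units.
#' @export
kld <- function(freqs, background = swissprot_background()) {
  if (any(background <= 0)) {
    it_stop("background frequencies must be strictly positive",
            "invalid_background")
  }
  if (abs(sum(freqs) - 1) > 1e-6) {
    it_stop("freqs must sum to 1", "invalid_input")
  }
  if (!is.null(names(freqs))) freqs <- freqs[AA_STANDARD]
  if (!is.null(names(background))) background <- background[AA_STANDARD]
  pos <- freqs > 0
  sum(freqs[pos] * log10(freqs[pos] / background[pos]))
}

#' Per-residue feature table
#'
#' Assembles one row per parent residue: amino-acid identity, KLD
#' conservation (from the MSA), deletion frequency (from pairwise
#' alignments), structure features (ASA, secondary structure, pLDDT from a
#' table or TSV path), and any number of amino-acid scale values.
#'
#' @param parent Parent protein string.
#' @param msa An `msa` (query must equal `parent`).
#' @param alignments List of `pairwise_alignment`s against `parent` (used
#'   for deletion frequencies), or an `indel_stats` object.
#' @param structure data.frame (or TSV path) with residue/aa/asa/ss/plddt.
#' @param scales Named list of named numeric residue scales (default
#'   [default_scales()]).
#' @param background Background for the KLD.
#' @return data.frame, one row per residue: residue, aa, kld,
#'   deletion_freq, asa, ss, plddt, and one column per scale.
#' @export
residue_feature_table <- function(parent, msa, alignments, structure,
                                  scales = default_scales(),
                                  background = swissprot_background()) {
  L <- nchar(parent)
  if (nchar(msa$query) != L) {
    it_stop("msa query length does not match parent", "shape_error")
  }
  stats <- if (inherits(alignments, "indel_stats")) alignments else
    indel_stats(alignments)
  if (nrow(stats$residues) != L) {
    it_stop("alignment query length does not match parent (indel stats)",
            "shape_error")
  }
  if (is.character(structure)) structure <- read_structure_tsv(structure)
  if (nrow(structure) != L) {
    it_stop("structure table length does not match parent", "shape_error")
  }
  aa <- strsplit(parent, "", fixed = TRUE)[[1]]
  kld_col <- vapply(seq_len(L), function(i)
    kld(column_frequencies(msa, i), background), numeric(1))
  out <- data.frame(residue = seq_len(L), aa = aa, kld = kld_col,
                    deletion_freq = stats$residues$deletion_freq,
                    asa = structure$asa, ss = structure$ss,
                    plddt = structure$plddt, stringsAsFactors = FALSE)
  for (nm in names(scales)) out[[nm]] <- unname(scales[[nm]][aa])
  out
}

#' Map residue features onto insertion sites
#'
#' Numeric residue features are assigned to site i as the mean of the two
#' residues flanking the insertion point (i and i+1). Categorical features
#' (amino-acid identity, secondary structure) become indicator columns in
#' which both flanking residues' categories are positive, so a site can
#' carry one or two positive labels per group. Site-native indel statistics
#' (insertion frequency, mean/median insertion length) are merged through
#' unchanged when supplied.
#'
#' @param residues data.frame from [residue_feature_table()] (>= 2 rows).
#' @param site_stats Optional `indel_stats` (its `sites` table) or a
#'   data.frame with a `site` column of site-native features.
#' @return data.frame, one row per site 1..L-1.
#' @export
map_to_sites <- function(residues, site_stats = NULL) {
  L <- nrow(residues)
  if (L < 2L) it_stop("need >= 2 residues", "invalid_input")
  i <- seq_len(L - 1L)
  out <- data.frame(site = i)
  num_cols <- setdiff(names(residues)[vapply(residues, is.numeric,
                                             logical(1))], "residue")
  for (nm in num_cols) {
    v <- residues[[nm]]
    out[[nm]] <- (v[i] + v[i + 1L]) / 2
  }
  # two-positive-label indicator encoding for categorical features
  for (spec in list(list(col = "aa", levels = AA_STANDARD, prefix = "aa_"),
                    list(col = "ss", levels = c("H", "E", "C"),
                         prefix = "ss_"))) {
    if (!spec$col %in% names(residues)) next
    v <- residues[[spec$col]]
    for (lev in spec$levels) {
      out[[paste0(spec$prefix, lev)]] <-
        as.integer(v[i] == lev | v[i + 1L] == lev)
    }
  }
  if (!is.null(site_stats)) {
    st <- if (inherits(site_stats, "indel_stats")) site_stats$sites else
      site_stats
    if (nrow(st) != L - 1L) {
      it_stop("site-native stats length does not match sites", "shape_error")
    }
    for (nm in setdiff(names(st), "site")) out[[nm]] <- st[[nm]]
  }
  out
}

#' Spearman correlation of each site feature with enrichment
#'
#' Rank correlation of every numeric feature column against the combined
#' enrichment score, over non-missing sites. Constant features are flagged
#' and reported as NA rather than raising an error.
#'
#' @param sites data.frame from [map_to_sites()].
#' @param profile An `enrichment_profile` over the same sites.
#' @return data.frame: feature, rho, n, constant.
#' @export
feature_correlations <- function(sites, profile) {
  if (nrow(sites) != length(profile$site)) {
    it_stop("feature table and profile cover different sites", "shape_error")
  }
  keep <- !profile$missing
  if (sum(keep) < 3L) it_stop("need >= 3 non-missing sites",
                              "insufficient_data")
  y <- profile$combined[keep]
  feats <- setdiff(names(sites)[vapply(sites, is.numeric, logical(1))],
                   "site")
  rows <- lapply(feats, function(nm) {
    x <- sites[[nm]][keep]
    constant <- length(unique(x)) == 1L
    rho <- if (constant) NA_real_ else
      suppressWarnings(cor(x, y, method = "spearman"))
    data.frame(feature = nm, rho = rho, n = sum(keep), constant = constant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
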