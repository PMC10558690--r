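#' Build an exact-match junction index for insertion-site calling
#'
#' For every candidate insertion site i (1..L-1, the parent residue
#' immediately preceding the insert) the index stores two diagnostic
#' signatures of width `2k`: the window of the insertion-variant CDS spanning
#' the 5' (parent->insert) junction and the one spanning the 3'
#' (insert->parent) junction, each with up to `k` nt on either side (shifted
#' inward near the termini). A read is assigned to a site iff it contains one
#' of these signatures exactly.
#'
#' Index construction fails if any signature is duplicated, or occurs inside
#' the plain parent or insert CDS — either would make exact-match calling
#' ambiguous.
#'
#' @param parent_cds Parent coding sequence (codon multiple).
#' @param insert_cds Insert coding sequence.
#' @param k Junction flank k-mer length in nt (default 18, minimum 12).
#' @return A `junction_index` object.
#' @export
build_junction_index <- function(parent_cds, insert_cds, k = 18) {
  parent_cds <- toupper(parent_cds)
  insert_cds <- toupper(insert_cds)
  if (nchar(parent_cds) %% 3L != 0L) {
    it_stop("parent_cds length must be a codon multiple", "invalid_config")
  }
  if (k < 12L) it_stop("junction k must be >= 12 nt", "invalid_config")
  if (nchar(insert_cds) < k) {
    it_stop("insert_cds must be at least k nt long", "invalid_config")
  }
  L <- nchar(parent_cds) %/% 3L
  if (L < 2L) it_stop("parent must have at least 2 codons", "invalid_config")
  jw <- junction_windows(parent_cds, insert_cds, k)
  uncovered <- setdiff(seq_len(L - 1L), jw$site[jw$valid])
  if (length(uncovered)) {
    it_stop(sprintf(
      "parent too short for k = %d: no full-flank junction at sites %s",
      k, paste(uncovered, collapse = ", ")), "invalid_config")
  }
  jw <- jw[jw$valid, , drop = FALSE]
  dup <- duplicated(jw$signature) | duplicated(jw$signature, fromLast = TRUE)
  if (any(dup)) {
    it_stop(sprintf(
      "ambiguous junction signatures (repeat sequence) at sites: %s",
      paste(sort(unique(jw$site[dup])), collapse = ", ")), "ambiguity_error")
  }
  sigs <- Biostrings::DNAStringSet(jw$signature)
  in_parent <- vapply(jw$signature, function(s)
    length(Biostrings::matchPattern(s, Biostrings::DNAString(parent_cds))) > 0,
    logical(1))
  in_insert <- vapply(jw$signature, function(s)
    length(Biostrings::matchPattern(s, Biostrings::DNAString(insert_cds))) > 0,
    logical(1))
  if (any(in_parent | in_insert)) {
    it_stop(sprintf(
      "junction signatures occur inside parent/insert at sites: %s",
      paste(sort(unique(jw$site[in_parent | in_insert])), collapse = ", ")),
      "ambiguity_error")
  }
  ins_probes <- substring(insert_cds,
                          seq_len(nchar(insert_cds) - k + 1L),
                          seq_len(nchar(insert_cds) - k + 1L) + k - 1L)
  idx <- list(parent_cds = parent_cds, insert_cds = insert_cds, k = k, L = L,
              sites = jw$site, orientation = jw$orientation,
              signatures = jw$signature,
              pdict = Biostrings::PDict(sigs),
              insert_pdict = Biostrings::PDict(
                Biostrings::DNAStringSet(unique(ins_probes))))
  class(idx) <- "junction_index"
  idx
}

#' @export
print.junction_index <- function(x, ...) {
  cat(sprintf("junction_index: %d sites, %d junction signatures, k = %d nt (width %d)\n",
              x$L - 1L, length(x$signatures), x$k, 2L * x$k))
  invisible(x)
}

DISCARD_REASONS <- c("no_insert", "corrupted", "ambiguous", "too_short")

#' Assign reads to insertion sites
#'
#' Vectorized exact-match calling: each read is scanned for the index's
#' junction signatures. A read matching signatures of exactly one site is
#' assigned there (matching both junctions of the same site counts once);
#' reads matching several sites are discarded as `ambiguous`; reads with no
#' junction match but insert-derived k-mer content are `corrupted` (e.g. a
#' sequencing error inside the junction window); reads with no insert content
#' are `no_insert`; reads shorter than one signature are `too_short`.
#'
#' @param reads A [Biostrings::DNAStringSet] or character vector.
#' @param index A `junction_index`.
#' @return data.frame with columns `site` (NA when discarded) and `reason`
#'   (NA when assigned).
#' @export
call_reads <- function(reads, index) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  n <- length(reads)
  site <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  w <- 2L * index$k
  short <- Biostrings::width(reads) < w
  reason[short] <- "too_short"
  ok <- which(!short)
  if (length(ok)) {
    hits <- Biostrings::vwhichPDict(index$pdict, reads[ok])
    nsites <- vapply(hits, function(h) length(unique(index$sites[h])),
                     integer(1))
    one <- nsites == 1L
    site[ok[one]] <- vapply(hits[one], function(h) index$sites[h[1L]],
                            integer(1))
    reason[ok[nsites > 1L]] <- "ambiguous"
    none <- ok[nsites == 0L]
    if (length(none)) {
      has_insert <- lengths(
        Biostrings::vwhichPDict(index$insert_pdict, reads[none])) > 0L
      reason[none] <- ifelse(has_insert, "corrupted", "no_insert")
    }
  }
  data.frame(site = site, reason = reason, stringsAsFactors = FALSE)
}

#' Per-site read counts for one pool
#'
#' Constructor for the per-pool count container. `counts` must cover sites
#' 1..L-1 and tallies must be consistent (`n_assigned + n_discarded =
#' n_total`, `sum(counts) = n_assigned`).
#'
#' @param counts Non-negative integer vector over sites 1..L-1.
#' @param n_total,n_discarded Read tallies.
#' @param discard_reasons Named tally per discard reason.
#' @param protein_id,replicate_id,condition,pool Metadata; `condition` one of
#'   dark/light/none, `pool` one of initial/sorted.
#' @return A `count_table` object.
#' @export
count_table <- function(counts, n_total = sum(counts),
                        n_discarded = n_total - sum(counts),
                        discard_reasons = integer(0),
                        protein_id = "protein", replicate_id = 1L,
                        condition = "none", pool = "initial") {
  counts <- as.integer(counts)
  if (any(counts < 0)) it_stop("counts must be non-negative", "invalid_input")
  n_assigned <- sum(counts)
  if (n_assigned + n_discarded != n_total) {
    it_stop("n_assigned + n_discarded must equal n_total", "invalid_input")
  }
  x <- list(counts = setNames(counts, seq_along(counts)),
            n_total = n_total, n_assigned = n_assigned,
            n_discarded = n_discarded,
            discard_reasons = discard_reasons,
            protein_id = protein_id, replicate_id = replicate_id,
            condition = condition, pool = pool)
  class(x) <- "count_table"
  x
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s/%s rep %s]: %d sites, %d/%d reads assigned\n",
              x$condition, x$pool, x$replicate_id, length(x$counts),
              x$n_assigned, x$n_total))
  invisible(x)
}

#' Count insertion sites in a read pool
#'
#' `count_reads()` tallies an in-memory read set; `count_library()` reads a
#' FASTQ(.gz) file first. Counting is order-independent and reads are never
#' assigned to more than one site.
#'
#' @param reads [Biostrings::DNAStringSet] (or character).
#' @param index A `junction_index`.
#' @inheritParams count_table
#' @return A [count_table()].
#' @export
count_reads <- function(reads, index, protein_id = "protein",
                        replicate_id = 1L, condition = "none",
                        pool = "initial") {
  calls <- call_reads(reads, index)
  counts <- tabulate(calls$site, nbins = index$L - 1L)
  reasons <- table(factor(calls$reason, levels = DISCARD_REASONS))
  count_table(counts, n_total = nrow(calls),
              n_discarded = sum(is.na(calls$site)),
              discard_reasons = setNames(as.integer(reasons),
                                         names(reasons)),
              protein_id = protein_id, replicate_id = replicate_id,
              condition = condition, pool = pool)
}

#' @rdname count_reads
#' @param fastq Path to a FASTQ or FASTQ.gz file.
#' @export
count_library <- function(fastq, index, protein_id = "protein",
                          replicate_id = 1L, condition = "none",
                          pool = "initial") {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) it_stop(sprintf("failed to parse FASTQ '%s': %s",
                                        fastq, conditionMessage(e)),
                                "parse_error"))
  count_reads(reads, index, protein_id = protein_id,
              replicate_id = replicate_id, condition = condition, pool = pool)
}

#' Write / read a count table as TSV (+ JSON sidecar)
#'
#' The TSV has header `site<TAB>count`; the sidecar (same path with
#' `.json` appended) stores the tallies and discard reasons.
#' @param x A `count_table`.
#' @param path Output TSV path.
#' @export
write_count_tsv <- function(x, path) {
  write.table(data.frame(site = as.integer(names(x$counts)),
                         count = as.integer(x$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x[c("n_total", "n_assigned", "n_discarded", "discard_reasons",
              "protein_id", "replicate_id", "condition", "pool")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  counts <- integer(max(tab$site))
  counts[tab$site] <- tab$count
  count_table(counts,
              n_total = meta$n_total %||% sum(counts),
              n_discarded = meta$n_discarded %||% 0L,
              discard_reasons = unlist(meta$discard_reasons) %||% integer(0),
              protein_id = meta$protein_id %||% "protein",
              replicate_id = meta$replicate_id %||% 1L,
              condition = meta$condition %||% "none",
              pool = meta$pool %||% "initial")
}
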