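#' Simulation configuration for a synthetic domain-insertion screen
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study conditions the pipeline is meant to operate under: a parent
#' protein of ~300 residues profiled at every internal insertion site, two
#' biological replicates, sequencing depths of 1e5 reads per pool, per-site
#' true log2 enrichment factors drawn from N(-3, 2^2) (placing ~93% of sites
#' below zero, in line with the strong depletion seen in insertion screens),
#' and junction-spanning single-end reads of 100 nt with a 0.1% per-base
#' substitution error rate.
#'
#' @param parent_length Parent protein length in residues (>= 10).
#' @param insert_cds Insert coding sequence (nucleotides, multiple of 3).
#' @param read_length Read length in nt; must be >= `2 * junction_k`.
#' @param junction_k Junction flank k-mer length in nt (see
#'   [build_junction_index()]).
#' @param depth_initial,depth_sorted Reads per initial / sorted pool.
#' @param substitution_error_rate Per-nucleotide substitution error
#'   probability.
#' @param n_replicates Number of biological replicates.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param enrichment_spec Distribution of per-site true log2 enrichment
#'   factors: `list(dist = "normal", mean, sd)` or
#'   `list(dist = "mixture", p_tolerated, mean_tol, sd_tol, mean_dep, sd_dep)`.
#' @param switch_spec Condition-dependent enrichment:
#'   `list(n_switch, delta)` — number of switch sites and absolute
#'   light-minus-dark log2 effect (signs alternate between ON and OFF).
#' @param homolog_spec Homolog family parameters: `list(n_homologs, max_sub_rate,
#'   ins_hotspot_frac, ins_rate_range, del_hotspot_frac, del_rate_range,
#'   ins_len_mean)`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for initial
#'   library abundances (uneven but near-complete coverage).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(parent_length = 300,
                              insert_cds = default_insert_cds(),
                              read_length = 100,
                              junction_k = 18,
                              depth_initial = 1e5,
                              depth_sorted = 1e5,
                              substitution_error_rate = 0.001,
                              n_replicates = 2,
                              seed = 1,
                              enrichment_spec = list(dist = "normal",
                                                     mean = -3, sd = 2),
                              switch_spec = list(n_switch = 0, delta = 4),
                              homolog_spec = list(n_homologs = 50,
                                                  max_sub_rate = 0.5,
                                                  ins_hotspot_frac = 0.15,
                                                  ins_rate_range = c(0.05, 0.3),
                                                  del_hotspot_frac = 0.15,
                                                  del_rate_range = c(0.05, 0.3),
                                                  ins_len_mean = 3),
                              dirichlet_alpha = 5) {
  cfg <- list(parent_length = as.integer(parent_length),
              insert_cds = toupper(insert_cds),
              read_length = as.integer(read_length),
              junction_k = as.integer(junction_k),
              depth_initial = depth_initial,
              depth_sorted = depth_sorted,
              substitution_error_rate = substitution_error_rate,
              n_replicates = as.integer(n_replicates),
              seed = seed,
              enrichment_spec = enrichment_spec,
              switch_spec = switch_spec,
              homolog_spec = homolog_spec,
              dirichlet_alpha = dirichlet_alpha)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$parent_length < 10L) {
    it_stop("parent_length must be >= 10 residues", "invalid_config")
  }
  if (nchar(cfg$insert_cds) %% 3L != 0L ||
      nchar(cfg$insert_cds) < cfg$junction_k) {
    it_stop("insert_cds must be a codon multiple at least junction_k long",
            "invalid_config")
  }
  if (cfg$read_length < 2L * cfg$junction_k) {
    it_stop("read_length must be >= 2 * junction_k so reads can span a junction",
            "invalid_config")
  }
  if (3L * cfg$parent_length + nchar(cfg$insert_cds) < cfg$read_length) {
    it_stop("insertion variants are shorter than read_length",
            "invalid_config")
  }
  if (cfg$depth_initial <= 0 || cfg$depth_sorted <= 0) {
    it_stop("sequencing depths must be positive", "invalid_config")
  }
  rate_in_01 <- function(x) all(x >= 0 & x <= 1)
  if (!rate_in_01(cfg$substitution_error_rate) ||
      !rate_in_01(cfg$homolog_spec$max_sub_rate) ||
      !rate_in_01(cfg$homolog_spec$ins_rate_range) ||
      !rate_in_01(cfg$homolog_spec$del_rate_range)) {
    it_stop("all rates must lie in [0, 1]", "invalid_config")
  }
  if (cfg$n_replicates < 1L) {
    it_stop("n_replicates must be >= 1", "invalid_config")
  }
  invisible(cfg)
}

#' Default synthetic insert coding sequence
#'
#' A fixed 86-codon synthetic insert CDS (roughly the size of a PDZ domain),
#' generated once from a fixed seed and constant across calls. Not a natural
#' domain sequence.
#'
#' @return A nucleotide string (length 258, codon multiple).
#' @export
default_insert_cds <- function() {
  aa <- with_seed(20240901, paste(
    sample(AA_STANDARD, 86, replace = TRUE, prob = swissprot_background()),
    collapse = ""))
  backtranslate(aa)
}

#' Back-translate a protein using the fixed codon table
#'
#' @param protein Amino-acid string over the standard alphabet.
#' @return Nucleotide CDS string; `translate_cds()` inverts it.
#' @export
backtranslate <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), AA_STANDARD)
  if (length(bad)) {
    it_stop(sprintf("nonstandard residues: %s", paste(bad, collapse = ",")),
            "invalid_config")
  }
  paste(CODON_TABLE[res], collapse = "")
}

#' @rdname backtranslate
#' @param cds Nucleotide CDS string (codon multiple).
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Generate a random parent protein and its CDS
#'
#' Residues are sampled i.i.d. from the Swiss-Prot background composition and
#' back-translated with one fixed codon per residue.
#'
#' @param length Protein length in residues (>= 10).
#' @param seed Integer seed.
#' @return `list(protein, cds)`; `translate_cds(cds)` equals `protein`.
#' @export
generate_parent <- function(length, seed) {
  if (length < 10) it_stop("parent length must be >= 10", "invalid_config")
  protein <- with_seed(seed, paste(
    sample(AA_STANDARD, length, replace = TRUE, prob = swissprot_background()),
    collapse = ""))
  list(protein = protein, cds = backtranslate(protein))
}

#' Simulate the ground truth of a domain-insertion screen
#'
#' Draws the parent sequence, per-site true log2 enrichment factors
#' (`log2_lambda`, sites 1..L-1), condition-dependent switch effects
#' (`switch_delta`), per-residue conservation weights and deletion rates, and
#' per-site insertion rates for the homolog family.
#'
#' @param config A [simulation_config()].
#' @return A `ground_truth` list.
#' @export
simulate_ground_truth <- function(config) {
  L <- config$parent_length
  par <- generate_parent(L, subseed(config$seed, 1))
  with_seed(subseed(config$seed, 2), {
    es <- config$enrichment_spec
    lambda <- switch(es$dist,
      normal = rnorm(L - 1, es$mean, es$sd),
      mixture = {
        tol <- runif(L - 1) < es$p_tolerated
        ifelse(tol, rnorm(L - 1, es$mean_tol, es$sd_tol),
                    rnorm(L - 1, es$mean_dep, es$sd_dep))
      },
      it_stop("unknown enrichment_spec dist", "invalid_config"))
    sw <- numeric(L - 1)
    ns <- config$switch_spec$n_switch
    if (ns > 0) {
      sites <- sample.int(L - 1, ns)
      signs <- rep_len(c(1, -1), ns)
      sw[sites] <- signs * config$switch_spec$delta
    }
    hs <- config$homolog_spec
    conservation <- rbeta(L, 2, 2)
    ins_rate <- ifelse(runif(L - 1) < hs$ins_hotspot_frac,
                       runif(L - 1, hs$ins_rate_range[1], hs$ins_rate_range[2]),
                       0)
    del_rate <- ifelse(runif(L) < hs$del_hotspot_frac,
                       runif(L, hs$del_rate_range[1], hs$del_rate_range[2]),
                       0)
    truth <- list(parent_protein = par$protein,
                  parent_cds = par$cds,
                  insert_cds = config$insert_cds,
                  log2_lambda = lambda,
                  switch_delta = sw,
                  conservation_weight = conservation,
                  insertion_rate = ins_rate,
                  deletion_rate = del_rate)
    class(truth) <- "ground_truth"
    truth
  })
}

#' Generate a homolog family with planted substitution and indel rates
#'
#' Each homolog is derived from the parent by independent per-residue
#' substitutions at rate `max_sub_rate * (1 - conservation_weight)`,
#' per-residue deletions at the planted `deletion_rate`, and insertions
#' between residues i and i+1 at the planted `insertion_rate` with
#' geometric(+1) lengths of mean `ins_len_mean`. The event log records every
#' planted edit.
#'
#' @param truth A `ground_truth` object.
#' @param spec Homolog spec (see [simulation_config()]); `spec$n_homologs >= 1`.
#' @param seed Integer seed.
#' @return `list(sequences, events)` where `sequences` is an
#'   [Biostrings::AAStringSet] and `events` a data.frame with columns
#'   homolog, type (`substitution`/`deletion`/`insertion`), position
#'   (residue for substitution/deletion, site for insertion), length.
#' @export
generate_homologs <- function(truth, spec, seed) {
  n <- spec$n_homologs
  if (is.null(n) || n < 1) it_stop("homolog_spec$n_homologs must be >= 1",
                                   "invalid_config")
  L <- nchar(truth$parent_protein)
  parent <- strsplit(truth$parent_protein, "", fixed = TRUE)[[1]]
  sub_rate <- spec$max_sub_rate * (1 - truth$conservation_weight)
  bg <- swissprot_background()
  ins_p <- 1 / max(spec$ins_len_mean, 1)
  with_seed(seed, {
    seqs <- character(n)
    ev <- vector("list", n)
    for (h in seq_len(n)) {
      del <- runif(L) < truth$deletion_rate
      sub <- !del & runif(L) < sub_rate
      ins <- c(runif(L - 1) < truth$insertion_rate, FALSE)
      res <- parent
      if (any(sub)) {
        repl <- sample(AA_STANDARD, sum(sub), replace = TRUE, prob = bg)
        # rejection: substitution must change the residue
        while (any(same <- repl == parent[sub])) {
          repl[same] <- sample(AA_STANDARD, sum(same), replace = TRUE,
                               prob = bg)
        }
        res[sub] <- repl
      }
      res[del] <- ""
      ins_chr <- character(L)
      ins_len <- integer(0)
      if (any(ins)) {
        ins_len <- 1L + rgeom(sum(ins), ins_p)
        ins_chr[ins] <- vapply(ins_len, function(k)
          paste(sample(AA_STANDARD, k, replace = TRUE, prob = bg),
                collapse = ""), character(1))
      }
      seqs[h] <- paste(paste0(res, ins_chr), collapse = "")
      ev[[h]] <- rbind(
        if (any(sub)) data.frame(homolog = h, type = "substitution",
                                 position = which(sub), length = 1L),
        if (any(del)) data.frame(homolog = h, type = "deletion",
                                 position = which(del), length = 1L),
        if (any(ins)) data.frame(homolog = h, type = "insertion",
                                 position = which(ins), length = ins_len))
    }
    events <- do.call(rbind, ev)
    if (is.null(events)) {
      events <- data.frame(homolog = integer(0), type = character(0),
                           position = integer(0), length = integer(0))
    }
    sequences <- Biostrings::AAStringSet(setNames(seqs, paste0("hom", seq_len(n))))
    list(sequences = sequences, events = events)
  })
}

# Junction signature windows (width 2k, k nt on either side of the junction)
# in variant coordinates; shared by the simulator and the junction index so
# reads and index agree. An orientation is valid only when the parent-side
# flank has the full k nt: clipped flanks (a handful of nt at the termini)
# would collide with other junctions whose parent context happens to end the
# same way. Every site of a parent with >= 12 residues keeps at least one
# valid orientation at the default k.
junction_windows <- function(parent_cds, insert_cds, k) {
  plen <- nchar(parent_cds)
  ilen <- nchar(insert_cds)
  L <- plen %/% 3L
  w <- 2L * k
  sites <- seq_len(L - 1L)
  j <- 3L * sites
  valid5 <- j >= k
  valid3 <- plen - j >= k
  sig5 <- ifelse(valid5,
                 paste0(substring(parent_cds, j - k + 1L, j),
                        substring(insert_cds, 1L, k)),
                 NA_character_)
  sig3 <- ifelse(valid3,
                 paste0(substring(insert_cds, ilen - k + 1L, ilen),
                        substring(parent_cds, j + 1L, j + k)),
                 NA_character_)
  # window start in variant coordinates (variant = prefix + insert + suffix)
  start5 <- j - k + 1L
  start3 <- j + ilen - k + 1L
  data.frame(site = rep(sites, 2L),
             orientation = rep(c("5p", "3p"), each = L - 1L),
             signature = c(sig5, sig3),
             start = c(start5, start3),
             width = w,
             valid = c(valid5, valid3),
             variant_length = rep(plen + ilen, 2L))
}

variant_cds <- function(parent_cds, insert_cds, site) {
  j <- 3L * site
  paste0(substring(parent_cds, 1L, j), insert_cds,
         substring(parent_cds, j + 1L, nchar(parent_cds)))
}

#' Generate sequencing reads for a synthetic insertion screen
#'
#' Draws initial-pool variant abundances from a symmetric Dirichlet, applies
#' per-site enrichment factors `2^(log2_lambda + condition * switch_delta)`
#' (dark/none = 0, light = 1) to obtain sorted-pool abundances, samples
#' multinomial counts at the configured depths per replicate, and emits
#' junction-spanning single-end reads (uniformly placed windows of the
#' variant CDS guaranteed to contain a junction signature) with i.i.d.
#' substitution errors. Constant Q30 qualities are written when FASTQ output
#' is requested.
#'
#' @param truth A `ground_truth` object.
#' @param config A [simulation_config()].
#' @param conditions Character vector, subset of `c("none", "dark", "light")`.
#' @param out_dir If non-NULL, write one FASTQ per pool into this directory.
#' @param emit_reads If FALSE, skip read emission and return counts only
#'   (fast path for count-level analyses; `reads` is NULL in each pool).
#' @return A `sim_library` list: `p0` (initial abundances), and `pools`, a
#'   list of entries with fields condition, pool, replicate, counts (true
#'   per-site read counts), reads ([Biostrings::DNAStringSet], names carry
#'   the true site as `"r<N>_s<site>"`), fastq (path or NA).
#' @export
generate_library_reads <- function(truth, config, conditions = "none",
                                   out_dir = NULL, emit_reads = TRUE) {
  validate_simulation_config(config)
  L <- nchar(truth$parent_protein)
  k <- config$junction_k
  rl <- config$read_length
  jw <- junction_windows(truth$parent_cds, truth$insert_cds, k)
  vcds <- vapply(seq_len(L - 1L), function(i)
    variant_cds(truth$parent_cds, truth$insert_cds, i), character(1))
  # valid read-start range containing each signature window
  lo <- pmax(1L, jw$start + jw$width - rl)
  hi <- pmin(jw$start, jw$variant_length - rl + 1L)
  with_seed(subseed(config$seed, 3), {
    p0 <- rgamma(L - 1L, shape = config$dirichlet_alpha, rate = 1)
    p0 <- p0 / sum(p0)
    pools <- list()
    for (cond in conditions) {
      mult <- if (cond == "light") 1 else 0
      wts <- p0 * 2^(truth$log2_lambda + mult * truth$switch_delta)
      wts[is.na(wts)] <- 0
      q <- if (sum(wts) > 0) wts / sum(wts) else wts
      for (r in seq_len(config$n_replicates)) {
        cnt_i <- as.integer(rmultinom(1, config$depth_initial, p0))
        cnt_s <- as.integer(rmultinom(1, config$depth_sorted, q))
        for (pool in c("initial", "sorted")) {
          cnt <- if (pool == "initial") cnt_i else cnt_s
          reads <- if (emit_reads) {
            emit_reads(cnt, vcds, jw, lo, hi, rl,
                       config$substitution_error_rate)
          }
          entry <- list(condition = cond, pool = pool, replicate = r,
                        counts = setNames(cnt, seq_len(L - 1L)),
                        expected = if (pool == "initial") p0 else q,
                        reads = reads, fastq = NA_character_)
          if (!is.null(out_dir) && emit_reads) {
            dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
            fq <- file.path(out_dir,
                            sprintf("%s_%s_rep%d.fastq", cond, pool, r))
            Biostrings::writeXStringSet(
              reads, filepath = fq, format = "fastq",
              qualities = Biostrings::BStringSet(
                rep(strrep("?", rl), length(reads))))
            entry$fastq <- fq
          }
          pools[[length(pools) + 1L]] <- entry
        }
      }
    }
    out <- list(p0 = p0, pools = pools, truth = truth, config = config)
    class(out) <- "sim_library"
    out
  })
}

emit_reads <- function(counts, vcds, jw, lo, hi, rl, error_rate) {
  n <- sum(counts)
  if (n == 0L) return(Biostrings::DNAStringSet())
  site <- rep.int(seq_along(counts), counts)
  nsite <- length(counts)
  # pick a valid junction orientation per read, then a uniform window start
  v5 <- jw$valid[seq_len(nsite)]
  v3 <- jw$valid[nsite + seq_len(nsite)]
  rnd <- sample.int(2L, n, replace = TRUE)         # 1 = 5p, 2 = 3p
  ori <- ifelse(v5[site] & v3[site], rnd, ifelse(v5[site], 1L, 2L))
  row <- site + (ori - 1L) * nsite                 # row in jw (5p block first)
  start <- lo[row] + floor(runif(n) * (hi[row] - lo[row] + 1L))
  reads <- substring(vcds[site], start, start + rl - 1L)
  if (error_rate > 0) reads <- apply_read_errors(reads, error_rate)
  Biostrings::DNAStringSet(setNames(reads,
    sprintf("r%d_s%d", seq_len(n), site)))
}

apply_read_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  nerr <- rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0L)
  if (!length(idx)) return(reads)
  bases <- c("A", "C", "G", "T")
  sub <- strsplit(reads[idx], "", fixed = TRUE)
  for (t in seq_along(idx)) {
    pos <- sample.int(rl, nerr[idx[t]])
    cur <- sub[[t]][pos]
    new <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
    sub[[t]][pos] <- new
  }
  reads[idx] <- vapply(sub, paste, character(1), collapse = "")
  reads
}

#' Expected pool fractions under the planted enrichment model
#'
#' Returns the exact expected initial and sorted read fractions implied by
#' the initial abundances and the planted per-site factors. Feeding these
#' (times depth) through the enrichment equation recovers `log2_lambda` up to
#' the shared normalization constant — the simulator's testable identity.
#'
#' @param truth A `ground_truth`.
#' @param p0 Initial abundance vector (sums to 1).
#' @param condition `"none"`, `"dark"` or `"light"`.
#' @return `list(initial, sorted)` fraction vectors.
#' @export
expected_fractions <- function(truth, p0, condition = "none") {
  mult <- if (condition == "light") 1 else 0
  wts <- p0 * 2^(truth$log2_lambda + mult * truth$switch_delta)
  wts[is.na(wts)] <- 0
  list(initial = p0, sorted = wts / sum(wts))
}

#' Generate a synthetic per-residue structure feature table
#'
#' Emulates per-residue features extracted from a predicted structure:
#' secondary structure drawn as segments (helix/strand/coil), ASA from
#' SS-dependent gamma distributions, and pLDDT from SS-dependent normals
#' clipped to [0, 100]. With `plddt_coupling = c != 0`, pLDDT is instead
#' built as `75 + 12 * (c * z_tol + sqrt(1 - c^2) * noise)` where `z_tol` is
#' the standardized negative per-residue tolerance (mean of the adjacent
#' sites' `log2_lambda`), planting a structure-tolerance association for
#' classifier-recovery tests.
#'
#' @param truth A `ground_truth`.
#' @param seed Integer seed.
#' @param plddt_coupling Correlation-like coupling in [-1, 1]; 0 = none.
#' @return data.frame with columns residue, aa, asa, ss, plddt.
#' @export
generate_structure_table <- function(truth, seed, plddt_coupling = 0) {
  L <- nchar(truth$parent_protein)
  aa <- strsplit(truth$parent_protein, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    ss <- character(0)
    while (length(ss) < L) {
      type <- sample(c("H", "E", "C"), 1L, prob = c(0.35, 0.25, 0.40))
      len <- switch(type, H = 4L + rgeom(1L, 1 / 6), E = 3L + rgeom(1L, 1 / 3),
                    C = 2L + rgeom(1L, 1 / 3))
      ss <- c(ss, rep(type, len))
    }
    ss <- ss[seq_len(L)]
    scale_by_ss <- c(H = 18, E = 14, C = 38)
    asa <- rgamma(L, shape = 2, scale = scale_by_ss[ss])
    plddt <- ifelse(ss == "C", rnorm(L, 68, 10), rnorm(L, 85, 7))
    if (plddt_coupling != 0) {
      lam <- truth$log2_lambda
      lam[!is.finite(lam)] <- min(lam[is.finite(lam)], -10)
      lam_res <- vapply(seq_len(L), function(i) {
        s <- c(i - 1L, i)
        s <- s[s >= 1L & s <= L - 1L]
        mean(lam[s])
      }, numeric(1))
      z_tol <- -(lam_res - mean(lam_res)) / sd(lam_res)
      c0 <- plddt_coupling
      plddt <- 75 + 12 * (c0 * z_tol + sqrt(1 - c0^2) * rnorm(L))
    }
    plddt <- pmin(100, pmax(0, plddt))
    data.frame(residue = seq_len(L), aa = aa, asa = asa, ss = ss,
               plddt = plddt, stringsAsFactors = FALSE)
  })
}

#' Write / read a per-residue structure feature TSV
#'
#' Plain TSV with header `residue aa asa ss plddt`.
#' @param x data.frame as produced by [generate_structure_table()].
#' @param path File path.
#' @export
write_structure_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_tsv
#' @export
read_structure_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "aa", "asa", "ss", "plddt")
  if (!all(need %in% names(x))) {
    it_stop("structure TSV must have columns residue, aa, asa, ss, plddt",
            "parse_error")
  }
  x[need]
}
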