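#' Per-site log2 enrichment scores for one replicate
#'
#' For each insertion site i the score is
#' \deqn{log2[ (sorted_i / \sum sorted) / (initial_i / \sum initial) ]}
#' i.e. the log2 ratio of the site's read fraction after sorting to its
#' fraction in the initial library. Variants with reads in the initial pool
#' but none after sorting cannot be log2-scaled and receive the detection
#' floor (default -10, in the range of the lowest scores such screens
#' produce). Sites missing from the initial library are flagged and excluded
#' from all downstream statistics. The denominators are the pools' assigned
#' read totals, so multiplying all counts in a pool by a constant leaves
#' scores unchanged.
#'
#' @param initial,sorted [count_table()] objects (or bare non-negative count
#'   vectors over the same sites).
#' @param floor Detection-floor score in log2 units (default -10).
#' @return data.frame with columns site, score, floored, missing. `score` is
#'   NA at missing sites.
#' @export
compute_enrichment <- function(initial, sorted, floor = -10) {
  ci <- if (inherits(initial, "count_table")) initial$counts else
    as.numeric(initial)
  cs <- if (inherits(sorted, "count_table")) sorted$counts else
    as.numeric(sorted)
  if (length(ci) != length(cs)) {
    it_stop("initial and sorted tables cover different site ranges",
            "shape_error")
  }
  if (sum(ci) == 0) {
    it_stop("initial pool has no assigned reads", "degenerate_input")
  }
  if (sum(cs) == 0) {
    it_stop("sorted pool has no assigned reads", "degenerate_input")
  }
  fi <- ci / sum(ci)
  fs <- cs / sum(cs)
  missing <- ci == 0
  floored <- !missing & cs == 0
  score <- rep(NA_real_, length(ci))
  keep <- !missing & !floored
  score[keep] <- log2(fs[keep] / fi[keep])
  score[floored] <- floor
  data.frame(site = seq_along(ci), score = score, floored = floored,
             missing = missing)
}

#' Combine replicate enrichment scores into a profile
#'
#' The combined score is the arithmetic mean of the replicate scores per
#' site (floors applied per replicate before averaging). A site missing from
#' the initial library of any replicate is missing overall.
#'
#' @param replicates List of per-replicate data.frames from
#'   [compute_enrichment()].
#' @param protein_id,condition Metadata.
#' @param floor Floor value recorded on the profile.
#' @return An `enrichment_profile`: list with `site`, `rep_scores` (sites x
#'   replicates matrix), `combined`, `floored` (matrix), `missing`, `floor`,
#'   `condition`, `protein_id`.
#' @export
combine_replicates <- function(replicates, protein_id = "protein",
                               condition = "none", floor = -10) {
  if (!length(replicates)) it_stop("need >= 1 replicate", "invalid_input")
  ns <- vapply(replicates, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    it_stop("replicates cover different site ranges", "shape_error")
  }
  rep_scores <- do.call(cbind, lapply(replicates, `[[`, "score"))
  colnames(rep_scores) <- paste0("rep", seq_along(replicates))
  floored <- do.call(cbind, lapply(replicates, `[[`, "floored"))
  missing <- Reduce(`|`, lapply(replicates, `[[`, "missing"))
  combined <- rowMeans(rep_scores)
  combined[missing] <- NA_real_
  x <- list(site = replicates[[1]]$site, rep_scores = rep_scores,
            combined = combined, floored = floored, missing = missing,
            floor = floor, condition = condition, protein_id = protein_id)
  class(x) <- "enrichment_profile"
  x
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf(
    "enrichment_profile [%s, %s]: %d sites, %d replicates, %d missing, %d floored\n",
    x$protein_id, x$condition, length(x$site), ncol(x$rep_scores),
    sum(x$missing), sum(apply(x$floored, 1, any) & !x$missing)))
  invisible(x)
}

#' Pearson correlation between two replicates
#'
#' Computed over sites non-missing in both replicates; floored scores enter
#' at the floor value.
#'
#' @param profile An `enrichment_profile` with exactly 2 replicates (or a
#'   list of two [compute_enrichment()] data.frames).
#' @return Pearson r.
#' @export
replicate_correlation <- function(profile) {
  if (!inherits(profile, "enrichment_profile")) {
    profile <- combine_replicates(profile)
  }
  if (ncol(profile$rep_scores) != 2L) {
    it_stop("replicate_correlation requires exactly 2 replicates",
            "invalid_input")
  }
  keep <- !profile$missing
  if (sum(keep) < 3L) {
    it_stop("need >= 3 shared non-missing sites", "insufficient_data")
  }
  cor(profile$rep_scores[keep, 1L], profile$rep_scores[keep, 2L])
}

#' Fraction of depleted insertion sites
#'
#' Fraction of non-missing sites whose combined score is negative.
#'
#' @param profile An `enrichment_profile`.
#' @return Fraction in [0, 1].
#' @export
depleted_fraction <- function(profile) {
  s <- profile$combined[!profile$missing]
  mean(s < 0)
}

#' Write / read an enrichment profile TSV (+ JSON summary)
#'
#' TSV columns: `site`, one column per replicate, `combined`, `floored`
#' (any replicate), `missing`. The JSON sidecar stores the floor, replicate
#' Pearson r (when 2 replicates) and the depleted fraction.
#' @param x An `enrichment_profile`.
#' @param path Output TSV path.
#' @export
write_profile_tsv <- function(x, path) {
  df <- data.frame(site = x$site, x$rep_scores, combined = x$combined,
                   floored = apply(x$floored, 1, any), missing = x$missing)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(protein_id = x$protein_id, condition = x$condition,
               floor = x$floor,
               depleted_fraction = depleted_fraction(x))
  if (ncol(x$rep_scores) == 2L && sum(!x$missing) >= 3L) {
    summ$replicate_pearson_r <- replicate_correlation(x)
  }
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  repcols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  rep_scores <- as.matrix(df[repcols])
  floor <- meta$floor %||% -10
  floored <- !is.na(rep_scores) & rep_scores == floor
  x <- list(site = df$site, rep_scores = rep_scores, combined = df$combined,
            floored = floored, missing = df$missing, floor = floor,
            condition = meta$condition %||% "none",
            protein_id = meta$protein_id %||% "protein")
  class(x) <- "enrichment_profile"
  x
}

#' Score a simulated screen end to end
#'
#' Convenience wrapper: counts every pool of a [generate_library_reads()]
#' result with a junction index and combines replicates into one
#' `enrichment_profile` per condition.
#'
#' @param sim A `sim_library`.
#' @param index Optional `junction_index` (built from the truth by default).
#' @param floor Detection floor.
#' @param use_true_counts If TRUE, skip read calling and score the
#'   simulator's true per-pool counts (oracle path for tests).
#' @return Named list of `enrichment_profile`s, one per condition.
#' @export
score_simulated_screen <- function(sim, index = NULL, floor = -10,
                                   use_true_counts = FALSE) {
  if (is.null(index) && !use_true_counts) {
    index <- build_junction_index(sim$truth$parent_cds, sim$truth$insert_cds,
                                  sim$config$junction_k)
  }
  conds <- unique(vapply(sim$pools, `[[`, character(1), "condition"))
  out <- list()
  for (cond in conds) {
    reps <- sort(unique(vapply(Filter(function(p) p$condition == cond,
                                      sim$pools),
                               `[[`, numeric(1), "replicate")))
    per_rep <- lapply(reps, function(r) {
      get_pool <- function(pool) {
        for (p in sim$pools) {
          if (p$condition == cond && p$replicate == r && p$pool == pool) {
            return(p)
          }
        }
        it_stop("pool not found", "invalid_input")
      }
      tab <- function(p) {
        if (use_true_counts) {
          count_table(p$counts, condition = cond, replicate_id = r,
                      pool = p$pool)
        } else {
          count_reads(p$reads, index, condition = cond, replicate_id = r,
                      pool = p$pool)
        }
      }
      compute_enrichment(tab(get_pool("initial")), tab(get_pool("sorted")),
                         floor = floor)
    })
    out[[cond]] <- combine_replicates(per_rep, condition = cond,
                                      floor = floor)
  }
  out
}
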