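# shared in-code fixtures; everything is generated at test time

# unit-score substitution matrix: match +1, mismatch -1
toy_matrix <- function() {
  m <- matrix(-1, 20, 20, dimnames = list(AA_STANDARD, AA_STANDARD))
  diag(m) <- 1
  m
}

random_aa <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(AA_STANDARD, n, replace = TRUE), collapse = ""))
}

# small simulated screen shared across calling/enrichment tests
tiny_screen <- function(seed = 11, parent_length = 60, depth = 5000,
                        error = 0, n_replicates = 1, ...) {
  cfg <- simulation_config(parent_length = parent_length,
                           depth_initial = depth, depth_sorted = depth,
                           substitution_error_rate = error,
                           n_replicates = n_replicates, seed = seed, ...)
  truth <- simulate_ground_truth(cfg)
  sim <- generate_library_reads(truth, cfg)
  idx <- build_junction_index(truth$parent_cds, truth$insert_cds,
                              cfg$junction_k)
  list(cfg = cfg, truth = truth, sim = sim, idx = idx)
}

# hand-built enrichment profile from replicate score vectors
profile_from_scores <- function(..., floor = -10) {
  reps <- lapply(list(...), function(s) {
    data.frame(site = seq_along(s), score = s,
               floored = !is.na(s) & s == floor, missing = is.na(s))
  })
  combine_replicates(reps, floor = floor)
}

# synthetic site features whose labels follow a noisy threshold rule on a
# linear combination of "informative" columns; flip_rate is realized through
# additive noise on the decision score (boundary-concentrated label noise)
planted_dataset <- function(n, n_noise, seed, flip_rate = 0.1,
                            weights = c(1, 0.8, 0.8), pos_frac = 0.4) {
  withr::with_seed(seed, {
    info <- matrix(rnorm(n * length(weights)), n)
    colnames(info) <- paste0("info", seq_along(weights))
    noise <- matrix(rnorm(n * n_noise), n)
    colnames(noise) <- paste0("noise", seq_len(n_noise))
    s <- as.numeric(scale(info %*% weights))
    tau <- quantile(s, 1 - pos_frac)
    sigma <- calibrate_flip_sigma(s - tau, flip_rate)
    y <- as.integer(s - tau + rnorm(n, 0, sigma) > 0)
    list(X = cbind(info, noise), y = y, clean = as.integer(s > tau),
         informative = colnames(info))
  })
}

# sigma such that E[P(sign flip)] equals the target rate for margins d
calibrate_flip_sigma <- function(d, rate) {
  f <- function(sigma) mean(pnorm(-abs(d) / sigma)) - rate
  stats::uniroot(f, c(1e-6, 100))$root
}
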