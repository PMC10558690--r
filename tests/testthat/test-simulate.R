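test_that("generated parents have the requested length, translate back, and are deterministic", {
  p <- generate_parent(50, seed = 1)
  expect_equal(nchar(p$protein), 50)
  expect_equal(translate_cds(p$cds), p$protein)
  expect_identical(generate_parent(50, seed = 1), p)
  expect_false(identical(generate_parent(50, seed = 2)$protein, p$protein))
  expect_error(generate_parent(5, seed = 1), class = "invalid_config")
})

test_that("parent residue composition follows the sampling weights", {
  p <- generate_parent(10000, seed = 2)
  freq <- table(factor(strsplit(p$protein, "")[[1]], levels = AA_STANDARD))
  freq <- as.numeric(freq) / 10000
  expect_true(all(abs(freq - swissprot_background()) < 0.01))
})

test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(parent_length = 5), class = "invalid_config")
  expect_error(simulation_config(read_length = 20), class = "invalid_config")
  expect_error(simulation_config(depth_initial = 0), class = "invalid_config")
  expect_error(simulation_config(substitution_error_rate = 1.5),
               class = "invalid_config")
})

test_that("homologs reproduce the planted edit model", {
  cfg <- simulation_config(parent_length = 20, seed = 7)
  truth <- simulate_ground_truth(cfg)
  # zero rates -> every homolog identical to the parent
  t0 <- truth
  t0$conservation_weight[] <- 1   # substitution rate 0
  t0$insertion_rate[] <- 0
  t0$deletion_rate[] <- 0
  hom <- generate_homologs(t0, cfg$homolog_spec, seed = 1)
  expect_true(all(as.character(hom$sequences) == truth$parent_protein))
  expect_equal(nrow(hom$events), 0L)

  # deletion rate 1 at residue 5 -> all homologs lack residue 5
  t1 <- t0
  t1$deletion_rate[5] <- 1
  hom1 <- generate_homologs(t1, modifyList(cfg$homolog_spec, list(n_homologs = 20)),
                            seed = 2)
  expected <- paste0(substr(truth$parent_protein, 1, 4),
                     substr(truth$parent_protein, 6, 20))
  expect_true(all(as.character(hom1$sequences) == expected))

  expect_error(generate_homologs(truth, list(n_homologs = 0), seed = 1),
               class = "invalid_config")
})

test_that("planted insertion rates are recovered at binomial accuracy", {
  cfg <- simulation_config(parent_length = 20, seed = 7)
  truth <- simulate_ground_truth(cfg)
  truth$conservation_weight[] <- 1
  truth$deletion_rate[] <- 0
  truth$insertion_rate[] <- 0
  truth$insertion_rate[10] <- 0.3
  n <- 10000
  hom <- generate_homologs(truth, modifyList(cfg$homolog_spec, list(n_homologs = n)),
                           seed = 3)
  ins10 <- sum(hom$events$type == "insertion" & hom$events$position == 10)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(ins10 / n - 0.3), 3 * se)
  # and the sequences actually carry the insertions
  long <- nchar(as.character(hom$sequences)) > 20
  expect_equal(sum(long), ins10)
})

test_that("pool counts are conserved and identical seeds give identical output", {
  scr <- tiny_screen(seed = 5, depth = 4000)
  for (p in scr$sim$pools) {
    expect_equal(sum(p$counts),
                 if (p$pool == "initial") 4000 else 4000)
    expect_equal(sum(p$counts), length(p$reads))
  }
  scr2 <- tiny_screen(seed = 5, depth = 4000)
  expect_identical(as.character(scr$sim$pools[[2]]$reads),
                   as.character(scr2$sim$pools[[2]]$reads))
  expect_identical(scr$sim$p0, scr2$sim$p0)
})

test_that("scoring the expected fractions recovers the planted factors exactly up to a constant", {
  cfg <- simulation_config(parent_length = 120, seed = 9)
  truth <- simulate_ground_truth(cfg)
  withr::with_seed(1, p0 <- {
    x <- rgamma(119, 5); x / sum(x)
  })
  fr <- expected_fractions(truth, p0)
  sc <- compute_enrichment(fr$initial * 1e6, fr$sorted * 1e6)$score
  resid <- sc - truth$log2_lambda
  expect_lt(max(resid) - min(resid), 1e-9)
})

test_that("a null screen shows no spurious enrichment", {
  # lambda identically 0: initial and sorted pools come from one
  # distribution; a two-sample chi-square should be non-significant at the
  # 1% level in at least 95% of seeded runs
  cfg <- simulation_config(parent_length = 30, depth_initial = 3000,
                           depth_sorted = 3000, n_replicates = 1, seed = 1)
  pvals <- vapply(1:100, function(s) {
    cfg$seed <- s
    truth <- simulate_ground_truth(cfg)
    truth$log2_lambda[] <- 0
    sim <- generate_library_reads(truth, cfg, emit_reads = FALSE)
    suppressWarnings(chisq.test(rbind(sim$pools[[1]]$counts,
                                      sim$pools[[2]]$counts))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("a variant excluded from the sorted pool never appears in it", {
  cfg <- simulation_config(parent_length = 40, depth_initial = 3000,
                           depth_sorted = 3000, n_replicates = 1, seed = 13)
  truth <- simulate_ground_truth(cfg)
  truth$log2_lambda[7] <- -Inf
  sim <- generate_library_reads(truth, cfg)
  sorted <- sim$pools[[2]]
  expect_equal(unname(sorted$counts[7]), 0L)
  expect_false(any(grepl("_s7$", names(sorted$reads))))
})

test_that("strongly negative planted factors exercise the detection floor", {
  cfg <- simulation_config(parent_length = 60, depth_initial = 2e4,
                           depth_sorted = 2e4, n_replicates = 1, seed = 17)
  truth <- simulate_ground_truth(cfg)
  truth$log2_lambda[10] <- -30
  sim <- generate_library_reads(truth, cfg, emit_reads = FALSE)
  prof <- score_simulated_screen(sim, use_true_counts = TRUE)$none
  expect_equal(prof$combined[10], -10)
  expect_true(prof$floored[10, 1])
})

test_that("synthetic structure tables satisfy their schema", {
  cfg <- simulation_config(parent_length = 50, seed = 3)
  truth <- simulate_ground_truth(cfg)
  st <- generate_structure_table(truth, seed = 4)
  expect_equal(nrow(st), 50)
  expect_true(all(st$asa >= 0))
  expect_true(all(st$ss %in% c("H", "E", "C")))
  expect_true(all(st$plddt >= 0 & st$plddt <= 100))
  expect_identical(st, generate_structure_table(truth, seed = 4))
  # round trip through TSV
  path <- tempfile(fileext = ".tsv")
  write_structure_tsv(st, path)
  st2 <- read_structure_tsv(path)
  expect_equal(st2$ss, st$ss)
  expect_equal(st2$plddt, st$plddt, tolerance = 1e-8)
})

test_that("an uncoupled structure feature shows no association with tolerance", {
  cfg <- simulation_config(parent_length = 80, seed = 19)
  truth <- simulate_ground_truth(cfg)
  rhos <- vapply(1:60, function(s) {
    st <- generate_structure_table(truth, seed = 1000 + s)
    site_plddt <- (st$plddt[1:79] + st$plddt[2:80]) / 2
    cor(site_plddt, truth$log2_lambda, method = "spearman")
  }, numeric(1))
  # null band: mean near zero, comfortably inside +/- 3 SE of Spearman null
  se <- 1 / sqrt(79 - 1)
  expect_lt(abs(mean(rhos)), 3 * se / sqrt(60))
  expect_gt(mean(abs(rhos) < 3 * se), 0.95)
})

test_that("a planted pLDDT-tolerance coupling is visible downstream", {
  cfg <- simulation_config(parent_length = 100, seed = 23)
  truth <- simulate_ground_truth(cfg)
  st <- generate_structure_table(truth, seed = 5, plddt_coupling = 0.8)
  site_plddt <- (st$plddt[1:99] + st$plddt[2:100]) / 2
  expect_lt(cor(site_plddt, truth$log2_lambda, method = "spearman"), -0.4)
})
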