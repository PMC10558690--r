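make_msa <- function(query, rows) {
  structure(list(query = query,
                 profile = rbind(strsplit(query, "")[[1]],
                                 do.call(rbind, strsplit(rows, "")))),
            class = "msa")
}

test_that("column frequencies exclude gaps and renormalize", {
  m <- make_msa("AC", c("AC", "AC", "A-"))
  expect_equal(unname(column_frequencies(m, 1)["A"]), 1)
  # column {C, C, C, -} at position 2 -> C certain
  expect_equal(unname(column_frequencies(m, 2)["C"]), 1)

  m2 <- make_msa("AA", c("AA", "CA", "-A", "-A"))
  f <- column_frequencies(m2, 1)       # {A, A, C, -, -}
  expect_equal(unname(f["A"]), 2 / 3)
  expect_equal(unname(f["C"]), 1 / 3)
  expect_equal(sum(f), 1)
  expect_error(column_frequencies(m2, 3), class = "invalid_input")
})

test_that("the divergence matches its analytic values and properties", {
  u <- uniform_background()
  expect_equal(kld(u, u), 0, tolerance = 1e-12)
  conserved <- setNames(c(1, rep(0, 19)), AA_STANDARD)
  expect_equal(kld(conserved, u), log10(20), tolerance = 1e-12)
  half <- setNames(rep(0, 20), AA_STANDARD)
  half[c("W", "M")] <- 0.5
  expect_equal(kld(half, u), 1.0, tolerance = 1e-12)

  # order invariance and positivity
  withr::with_seed(1, {
    f <- rgamma(20, 1); f <- setNames(f / sum(f), AA_STANDARD)
  })
  perm <- sample(AA_STANDARD)
  expect_equal(kld(f[perm], swissprot_background()[perm]),
               kld(f, swissprot_background()))
  expect_gt(kld(f, swissprot_background()), 0)
  expect_error(kld(f, setNames(c(0, rep(1 / 19, 19)), AA_STANDARD)),
               class = "invalid_background")
  expect_error(kld(f * 2), class = "invalid_input")
})

test_that("an msa built from zero-divergence homolog alignments is unanimous", {
  cfg <- simulation_config(parent_length = 25, seed = 3)
  truth <- simulate_ground_truth(cfg)
  truth$conservation_weight[] <- 1
  truth$insertion_rate[] <- 0
  truth$deletion_rate[] <- 0
  hom <- generate_homologs(truth, modifyList(cfg$homolog_spec, list(n_homologs = 6)),
                           seed = 1)
  aln <- align_homologs(truth$parent_protein, hom$sequences)
  m <- msa_from_alignments(aln)
  for (i in seq_len(25)) {
    expect_equal(max(column_frequencies(m, i)), 1)
  }
})

test_that("indel statistics match a hand-built alignment set", {
  q <- random_aa(20, seed = 42)
  # one homolog with a 3-residue insertion between residues 10 and 11, in a
  # low-similarity-proof way: insert WWW into a W-free query
  stopifnot(!grepl("W", q))
  hom_ins <- paste0(substr(q, 1, 10), "WWW", substr(q, 11, 20))
  homs <- c(hom_ins, q, q, q)
  aln <- align_homologs(q, homs)
  st <- indel_stats(aln)
  expect_equal(st$sites$insertion_freq[10], 0.25)
  expect_equal(st$sites$mean_ins_len[10], 3)
  expect_equal(st$sites$median_ins_len[10], 3)
  expect_equal(sum(st$sites$insertion_freq), 0.25)
  expect_true(all(st$residues$deletion_freq == 0))

  # all-identical homologs -> all zero
  st0 <- indel_stats(align_homologs(q, c(q, q)))
  expect_true(all(st0$sites$insertion_freq == 0))
  expect_true(all(st0$sites$mean_ins_len == 0))
  expect_error(indel_stats(list(align_pair(q, q),
                                align_pair(random_aa(10, 1), q))),
               class = "invalid_input")
})

test_that("planted indel rates are recovered from recomputed alignments", {
  cfg <- simulation_config(parent_length = 40, seed = 31)
  truth <- simulate_ground_truth(cfg)
  truth$conservation_weight[] <- 1   # no substitutions: alignment unambiguous
  truth$insertion_rate[] <- 0
  truth$deletion_rate[] <- 0
  truth$insertion_rate[15] <- 0.25
  truth$deletion_rate[30] <- 0.2
  n <- 1000
  hom <- generate_homologs(truth, modifyList(cfg$homolog_spec, list(n_homologs = n)),
                           seed = 5)
  st <- indel_stats(align_homologs(truth$parent_protein, hom$sequences))
  expect_lt(abs(st$sites$insertion_freq[15] - 0.25),
            3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(st$residues$deletion_freq[30] - 0.2),
            3 * sqrt(0.2 * 0.8 / n))
  expect_true(all(st$sites$insertion_freq >= 0 &
                  st$sites$insertion_freq <= 1))
})

test_that("the residue feature table composes its ingredients faithfully", {
  cfg <- simulation_config(parent_length = 30, seed = 37)
  truth <- simulate_ground_truth(cfg)
  hom <- generate_homologs(truth, modifyList(cfg$homolog_spec, list(n_homologs = 10)),
                           seed = 2)
  aln <- align_homologs(truth$parent_protein, hom$sequences)
  m <- msa_from_alignments(aln)
  st <- generate_structure_table(truth, seed = 3)
  scales <- c(default_scales(), list(const = setNames(rep(2, 20),
                                                      AA_STANDARD)))
  tab <- residue_feature_table(truth$parent_protein, m, aln, st,
                               scales = scales)
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$kld >= 0))
  expect_true(all(tab$ss %in% c("H", "E", "C")))
  expect_equal(tab$const, rep(2, 30))  # constant scale propagates
  # compositional check: the KLD column equals kld(column_frequencies(.))
  manual <- vapply(seq_len(30), function(i)
    kld(column_frequencies(m, i)), numeric(1))
  expect_equal(tab$kld, manual)
  expect_error(residue_feature_table(truth$parent_protein, m, aln,
                                     st[1:10, ]), class = "shape_error")
})

test_that("site mapping takes flanking means and two-positive categorical labels", {
  res <- data.frame(residue = 1:3, aa = c("A", "C", "A"), val = c(2, 4, 8),
                    ss = c("H", "E", "H"), stringsAsFactors = FALSE)
  s <- map_to_sites(res)
  expect_equal(s$val, c(3, 6))
  expect_equal(s$ss_H, c(1L, 1L))
  expect_equal(s$ss_E, c(1L, 1L))
  expect_equal(s$ss_C, c(0L, 0L))
  expect_equal(s$aa_A, c(1L, 1L))
  expect_equal(s$aa_C, c(1L, 1L))
  res2 <- data.frame(residue = 1:2, aa = c("A", "A"), val = c(1, 1),
                     ss = c("H", "H"), stringsAsFactors = FALSE)
  s2 <- map_to_sites(res2)
  expect_equal(s2$ss_H, 1L)
  expect_equal(s2$ss_E, 0L)
  # linearity of the numeric mapping
  resA <- data.frame(residue = 1:4, v = c(1, 5, 2, 7))
  resB <- data.frame(residue = 1:4, v = c(10, 0, 4, 2))
  resAB <- data.frame(residue = 1:4, v = resA$v + resB$v)
  expect_equal(map_to_sites(resAB)$v,
               map_to_sites(resA)$v + map_to_sites(resB)$v)
  expect_error(map_to_sites(res[1, , drop = FALSE]), class = "invalid_input")
})

test_that("feature correlations rank-correlate against combined scores", {
  prof <- profile_from_scores(c(-8, -2, 0.5, 3, -1, 2))
  sites <- data.frame(site = 1:6, same = prof$combined,
                      anti = -prof$combined, flat = rep(1, 6))
  fc <- feature_correlations(sites, prof)
  expect_equal(fc$rho[fc$feature == "same"], 1)
  expect_equal(fc$rho[fc$feature == "anti"], -1)
  expect_true(fc$constant[fc$feature == "flat"])
  expect_true(is.na(fc$rho[fc$feature == "flat"]))
})

test_that("uncoupled structure features stay inside the correlation null band", {
  cfg <- simulation_config(parent_length = 150, seed = 43)
  truth <- simulate_ground_truth(cfg)
  prof <- profile_from_scores(truth$log2_lambda)
  rhos <- vapply(1:60, function(s) {
    st <- generate_structure_table(truth, seed = 2000 + s)
    sites <- map_to_sites(st[, c("residue", "asa", "plddt")])
    feature_correlations(sites, prof)$rho
  }, numeric(2))
  # centred on zero, small in magnitude (flanking means leave neighbouring
  # sites correlated, so the band is wider than an i.i.d. null)
  expect_lt(max(abs(rowMeans(rhos))), 0.05)
  expect_lt(mean(abs(rhos)), 0.15)
})

test_that("AAindex scale files parse to complete residue vectors", {
  scales <- default_scales()
  expect_named(scales, c("KYTJ820101", "SYNLNK0001"))
  kd <- scales$KYTJ820101
  expect_equal(unname(kd["I"]), 4.5)
  expect_equal(unname(kd["R"]), -4.5)
  expect_equal(unname(kd["G"]), -0.4)
  expect_length(kd, 20)
  expect_error(read_aaindex(tempfile()), class = "parse_error")
})
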