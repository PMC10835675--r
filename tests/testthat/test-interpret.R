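test_that("attention aggregation conserves softmax mass and is additive", {
  m <- tiny_model(seed = 31)
  set.seed(32)
  seqs <- random_dna(5, 14)   # 12 tokens + <cls>
  att <- attention_scores(m, seqs, per_sequence = TRUE)
  T_tok <- 14 - 3 + 1 + 1
  # every sequence contributes exactly its query count per head
  expect_lt(max(abs(att$per_sequence$forward - T_tok)), 1e-4)
  expect_lt(max(abs(att$per_sequence$reverse - T_tok)), 1e-4)
  # doubling the dataset doubles the aggregate
  att2 <- attention_scores(m, c(seqs, seqs))
  expect_equal(att2$forward, 2 * att$forward, tolerance = 1e-10)
  expect_equal(att2$reverse, 2 * att$reverse, tolerance = 1e-10)
})

test_that("forward and reverse encoders develop distinct attention", {
  fit <- trained_small_model()
  sub <- fit$panel$probes[1:40, ]
  class(sub) <- class(fit$panel$probes)
  att <- attention_scores(fit$model, sub)
  # the aggregated score is conserved (both branches equal n * T), so the
  # branch comparison uses the concentration profile, which is free to —
  # and for untied trained encoders does — differ
  expect_equal(att$forward, att$reverse, tolerance = 1e-4)
  rel_gap <- max(abs(att$forward_conc - att$reverse_conc) /
                   (abs(att$forward_conc) + abs(att$reverse_conc)))
  expect_gt(rel_gap, 1e-4)
  df <- as.data.frame(att)
  expect_equal(nrow(df),
               2 * fit$model$config$n_layers * fit$model$config$n_heads)
  expect_true(all(df$score >= 0))
  expect_true(all(df$concentration >= 0))
})

test_that("path-integral attribution is exact for linear functions", {
  set.seed(41)
  w <- rnorm(20)
  x <- rnorm(20)
  b <- rep(0, 20)
  ig <- ig_riemann(function(z) w, x, b, steps = 8)
  expect_equal(ig, w * x, tolerance = 1e-12)
  # nonzero baseline: attribution is w * (x - b), completeness exact
  b2 <- rnorm(20)
  ig2 <- ig_riemann(function(z) w, x, b2, steps = 8)
  expect_equal(sum(ig2), sum(w * x) - sum(w * b2), tolerance = 1e-12)
})

test_that("a constant model attributes nothing", {
  fit <- trained_small_model()
  m0 <- fit$model
  m0$params$head.Wout[] <- 0
  m0$params$head.bout <- 0
  a <- integrated_gradients(m0, fit$panel$probes$sequence[1], steps = 16)
  expect_equal(max(abs(a$ig_values)), 0, tolerance = 1e-6)
  expect_equal(a$completeness_gap, 0, tolerance = 1e-6)
})

test_that("integrated gradients satisfy completeness on a trained model", {
  fit <- trained_small_model()
  set.seed(42)
  idx <- sample(nrow(fit$panel$probes), 8)
  for (i in idx) {
    a <- integrated_gradients(fit$model, fit$panel$probes$sequence[i],
                              steps = 64)
    span <- abs(a$prediction - a$baseline_prediction)
    expect_lt(abs(a$completeness_gap), 0.05 * span + 1e-3)
    expect_length(a$ig_values, 40 - 3 + 1 + 1)
  }
  expect_error(integrated_gradients(fit$model, "ACGTACGT", steps = 4),
               "steps")
})

test_that("positional importance averages |IG| per position", {
  fit <- trained_small_model()
  sub <- fit$panel$probes[1:6, ]
  class(sub) <- class(fit$panel$probes)
  attrs <- integrated_gradients_set(fit$model, sub, steps = 16)
  prof <- positional_importance(attrs)
  expect_equal(nrow(prof), length(attrs[[1]]$ig_values))
  expect_equal(prof$token[1], "<cls>")
  M <- vapply(attrs, function(a) abs(a$ig_values), numeric(nrow(prof)))
  expect_equal(prof$mean_abs_ig, rowMeans(M))
  # all-zero attributions give an all-zero profile
  zeroed <- lapply(attrs, function(a) { a$ig_values[] <- 0; a })
  expect_equal(positional_importance(zeroed)$mean_abs_ig,
               rep(0, nrow(prof)))
  # ragged lengths are refused with guidance
  short <- integrated_gradients(fit$model, "ACGTACGTACGT", steps = 16)
  expect_error(positional_importance(c(attrs, list(short))), "group")
})

test_that("extreme-depth extraction cuts standard-normal tails", {
  thr <- extreme_depth_sets(rnorm(10), rate = 0.05)$thresholds
  expect_equal(unname(thr), c(qnorm(0.05), qnorm(0.95)), tolerance = 1e-12)
  expect_equal(unname(thr[2]), 1.644854, tolerance = 1e-6)

  set.seed(43)
  z <- setNames(rnorm(2000), sprintf("p%d", 1:2000))
  e5 <- extreme_depth_sets(z, 0.05)
  e10 <- extreme_depth_sets(z, 0.10)
  # monotone in rate: larger rate gives supersets
  expect_true(all(e5$high %in% e10$high))
  expect_true(all(e5$low %in% e10$low))
  expect_error(extreme_depth_sets(z, 0.6), "rate")
  expect_error(extreme_depth_sets(z, 0), "rate")
})

test_that("k-mer enrichment ratios behave under forced compositions", {
  set.seed(44)
  bg <- random_dna(80, 30)
  even <- kmer_enrichment(bg, bg, k = 3)
  expect_equal(even$ratio, rep(1, 64), tolerance = 1e-12)
  expect_equal(sum(even$freq_subset), 1, tolerance = 1e-12)

  polyC <- rep(strrep("C", 30), 10)
  enr <- kmer_enrichment(polyC, bg, k = 3)
  expect_equal(enr$kmer[1], "CCC")
  expect_gt(enr$ratio[1], 10)
  expect_error(kmer_enrichment(character(0), bg), "empty")
})

test_that("composition summary reports base and dinucleotide frequencies", {
  comp <- sequence_composition(c("CCTT", "CTCT"))
  expect_equal(sum(comp$base), 1, tolerance = 1e-12)
  expect_equal(sum(comp$dinucleotide), 1, tolerance = 1e-12)
  expect_equal(unname(comp$base["C"]), 0.5)
  expect_equal(unname(comp$dinucleotide["CT"]), 3 / 6, tolerance = 1e-12)
})

test_that("thermodynamic rank correlation is Kendall's tau-b", {
  ids <- sprintf("p%02d", 1:20)
  x <- setNames(seq(0.1, 2, length.out = 20), ids)
  tab <- data.frame(probe_id = ids, free_energy = seq_len(20),
                    stability = rev(seq_len(20)))
  res <- thermo_correlation(x, tab)
  expect_equal(res$kendall_tau[res$metric == "free_energy"], 1)
  expect_equal(res$kendall_tau[res$metric == "stability"], -1)

  set.seed(45)
  n <- 1000
  ids2 <- sprintf("q%04d", 1:n)
  res2 <- thermo_correlation(setNames(rnorm(n), ids2),
                             data.frame(probe_id = ids2, noise = rnorm(n)))
  expect_lt(abs(res2$kendall_tau), 0.08)  # independent columns

  expect_error(thermo_correlation(x[1:5], tab), ">= 10")
  expect_error(thermo_correlation(x, data.frame(probe_id = ids,
                                                flat = rep(1, 20))),
               "tied")
})

test_that("motif-covering token positions are located correctly", {
  # CTT at positions 5-7 of a 12-mer: windows 3..7 overlap it (k = 3)
  s <- "AAAACTTAAAAA"
  expect_equal(motif_token_positions(s, "CTT", k = 3, prepend_cls = FALSE),
               3:7)
  expect_equal(motif_token_positions(s, "CTT", k = 3, prepend_cls = TRUE),
               4:8)
  expect_length(motif_token_positions("AAAAAAAA", "CTT", 3), 0)
})
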