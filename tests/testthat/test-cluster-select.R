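# hand-built frequency object covering only the fields delta_eg and
# select_contrast read
make_freqs <- function(major_freq, sub_freq, major_rr, sub_rr, sub_to_major,
                       sub_sizes = rep(5, nrow(sub_freq))) {
  structure(list(
    major = list(gene_freq = major_freq, recurrence_rate = major_rr,
                 mean_dysregulated = rowSums(major_freq),
                 size = rep(10, nrow(major_freq))),
    sub = list(gene_freq = sub_freq, recurrence_rate = sub_rr,
               mean_dysregulated = rowSums(sub_freq), size = sub_sizes),
    sub_to_major = sub_to_major
  ), class = "cluster_gene_frequency")
}

test_that("perfectly separable blocks are recovered exactly", {
  calls <- rbind(matrix(rep(c(1L, 0L), c(5, 5)), nrow = 6, ncol = 10,
                        byrow = TRUE),
                 matrix(rep(c(0L, 1L), c(5, 5)), nrow = 6, ncol = 10,
                        byrow = TRUE))
  rownames(calls) <- sprintf("p%02d", 1:12)
  colnames(calls) <- sprintf("g%02d", 1:10)
  asg <- cluster_patients(calls, k_major = 2, k_sub = 2)
  expect_identical(length(unique(asg$major[1:6])), 1L)
  expect_identical(length(unique(asg$major[7:12])), 1L)
  expect_false(asg$major[1] == asg$major[7])
  # trivial cut: every patient its own cluster
  singletons <- cluster_patients(calls, k_major = 12, k_sub = 12)
  expect_identical(length(unique(singletons$major)), 12L)
  expect_error(cluster_patients(calls, k_major = 5, k_sub = 3), "k_major")
})

test_that("subclusters nest within major clusters", {
  set.seed(11)
  calls <- matrix(rbinom(40 * 12, 1, 0.3), nrow = 40,
                  dimnames = list(sprintf("p%02d", 1:40),
                                  sprintf("g%02d", 1:12)))
  asg <- cluster_patients(calls, k_major = 3, k_sub = 8)
  nesting <- tapply(asg$major, asg$sub, function(m) length(unique(m)))
  expect_true(all(nesting == 1))
})

test_that("clustering is invariant under patient permutation (ARI = 1)", {
  co <- generate_cohort(simulation_config(n_patients = 200, seed = 12))
  cuts <- gene_cutoffs(co$expression, co$clinical)
  calls <- call_dysregulation(co$expression, cuts)
  a <- cluster_patients(calls)
  set.seed(13)
  perm <- sample(nrow(calls))
  b <- cluster_patients(calls[perm, ])
  expect_equal(adjusted_rand_index(a$major, b$major[names(a$major)]), 1)
})

test_that("cluster frequencies match manual counting on a six-patient toy", {
  calls <- matrix(c(1, 1, 0,
                    1, 0, 0,
                    1, 1, 1,
                    0, 0, 0,
                    0, 1, 0,
                    0, 0, 0), nrow = 6, byrow = TRUE,
                  dimnames = list(sprintf("p%d", 1:6), c("g1", "g2", "g3")))
  asg <- structure(list(
    major = setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(calls)),
    sub = setNames(c(1L, 1L, 2L, 3L, 3L, 4L), rownames(calls)),
    sub_to_major = setNames(c(1L, 1L, 2L, 2L), as.character(1:4)),
    k_major = 2, k_sub = 4), class = "cluster_assignment")
  clin <- make_clinical(6, event = c(1, 0, 1, 0, 0, 0))
  fr <- cluster_frequencies(calls, asg, clin)
  expect_equal(unname(fr$major$gene_freq["1", ]), c(1, 2 / 3, 1 / 3))
  expect_equal(unname(fr$major$gene_freq["2", ]), c(0, 1 / 3, 0))
  expect_equal(unname(fr$major$recurrence_rate), c(2 / 3, 0))
  expect_equal(unname(fr$major$mean_dysregulated), c(2, 1 / 3))
  # conservation: sizes x frequencies reproduce the total call counts
  expect_equal(colSums(fr$major$gene_freq * fr$major$size), colSums(calls))
  expect_error(cluster_frequencies(calls, asg, make_clinical(3)), "missing")
})

test_that("delta-EG arithmetic, selection threshold and antisymmetry", {
  gf_major <- rbind("1" = c(0.5, 0.2, 0.1), "2" = c(0.4, 0.2, 0.0))
  colnames(gf_major) <- c("gA", "gB", "gC")
  gf_sub <- rbind("s1" = c(0.9, 0.2, 1.0))
  colnames(gf_sub) <- colnames(gf_major)
  fr <- make_freqs(gf_major, gf_sub, c("1" = 0.1, "2" = 0.2),
                   c(s1 = 0.8), c(s1 = 1L))
  res <- delta_eg(fr, "s1", c("1", "2"), threshold = 0.3)
  expect_equal(res$mean_delta, c(0.45, 0, 0.95))
  expect_identical(res$selected, c(TRUE, FALSE, TRUE))
  # swapping target and a reference negates that delta
  gf_sub2 <- rbind("s2" = gf_major["1", ])
  fr2 <- make_freqs(rbind("3" = gf_sub["s1", ], "2" = gf_major["2", ]),
                    gf_sub2, c("3" = 0.8, "2" = 0.2), c(s2 = 0.1),
                    c(s2 = 3L))
  res2 <- delta_eg(fr2, "s2", c("3", "2"), threshold = 0.3)
  expect_equal(res2$delta_vs_ref1, -res$delta_vs_ref1)
  expect_error(delta_eg(fr, "nope", c("1", "2")), "unknown target")
  expect_error(delta_eg(fr, "s1", c("1", "9")), "unknown reference")
})

test_that("the contrast picker finds the high-recurrence subcluster and low refs", {
  gf_major <- matrix(0.1, 3, 2,
                     dimnames = list(c("1", "2", "3"), c("gA", "gB")))
  gf_sub <- matrix(0.1, 4, 2,
                   dimnames = list(c("s1", "s2", "s3", "s4"), c("gA", "gB")))
  fr <- make_freqs(gf_major, gf_sub,
                   major_rr = c("1" = 0.05, "2" = 0.60, "3" = 0.10),
                   sub_rr = c(s1 = 0.0, s2 = 0.5, s3 = 0.9, s4 = 0.1),
                   sub_to_major = setNames(c(1L, 2L, 2L, 3L),
                                           c("s1", "s2", "s3", "s4")),
                   sub_sizes = c(5, 5, 5, 5))
  ct <- select_contrast(fr)
  expect_identical(ct$target, "s3")  # hottest subcluster of hottest cluster
  expect_setequal(ct$refs, c("1", "3"))
})

test_that("Spearman subcluster correlation: monotone, reversed and tied cases", {
  gf <- matrix(0, 5, 1, dimnames = list(paste0("s", 1:5), "g"))
  base <- list(gene_freq = gf, size = rep(4, 5))
  up <- structure(list(major = base, sub = c(base, list(
    mean_dysregulated = c(1, 2, 3, 4, 5),
    recurrence_rate = c(0.1, 0.2, 0.3, 0.4, 0.5))),
    sub_to_major = NULL), class = "cluster_gene_frequency")
  up$sub$gene_freq <- gf
  r <- frequency_recurrence_correlation(up)
  expect_equal(r$rho, 1)
  # exact permutation p: only the identity and the full reversal of 5
  # distinct ranks reach |rho| = 1
  expect_equal(r$p_value, 2 / factorial(5))

  down <- up
  down$sub$recurrence_rate <- rev(down$sub$recurrence_rate)
  expect_equal(frequency_recurrence_correlation(down)$rho, -1)

  tied <- up
  tied$sub$mean_dysregulated <- c(1, 2, 2, 4, 5)
  tied$sub$recurrence_rate <- c(0.1, 0.3, 0.2, 0.4, 0.5)
  # hand rank computation with midranks
  rx <- rank(tied$sub$mean_dysregulated)
  ry <- rank(tied$sub$recurrence_rate)
  expect_equal(frequency_recurrence_correlation(tied)$rho,
               sum((rx - mean(rx)) * (ry - mean(ry))) /
                 sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2)))

  flat <- up
  flat$sub$recurrence_rate <- rep(0.2, 5)
  expect_warning(fc <- frequency_recurrence_correlation(flat), "undefined")
  expect_true(is.na(fc$rho))
})

test_that("the adjusted Rand index agrees with an established implementation", {
  set.seed(14)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(rep(1:2, 5), rep(2:1, 5)), 1)
})
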