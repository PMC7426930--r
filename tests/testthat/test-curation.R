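# build a divergence_matrix directly from numbers, for rule-level tests
dm_from <- function(d, species, labels = NULL) {
  n <- nrow(d)
  if (is.null(labels)) labels <- sprintf("s%02d", seq_len(n))
  ns <- matrix(1000L, n, n); diag(ns) <- 0L
  divergence_matrix(labels, species, d, ns, min_overlap = 100)
}

sym <- function(v, n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- v
  d + t(d)
}

test_that("threshold comparisons are accept-<=/flag-> within species", {
  # exactly t: accepted (the screen's inequality direction)
  d <- sym(0.03, 2)
  expect_equal(nrow(flag_intraspecific(dm_from(d, rep("Xa ya", 2)), t = 0.03)), 0L)
  # just above t: flagged
  d2 <- sym(0.030001, 2)
  fl <- flag_intraspecific(dm_from(d2, rep("Xa ya", 2)), t = 0.03)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$category, "intraspecific_divergent")
})

test_that("threshold comparisons are accept->/flag-<= within genera", {
  sp <- c("Xa ya", "Xa za")
  # exactly t: flagged (both members of the pair)
  fl <- flag_intrageneric(dm_from(sym(0.03, 2), sp), t = 0.03)
  expect_equal(nrow(fl), 2L)
  expect_equal(unique(fl$category), "intrageneric_similar")
  # just above t: accepted
  expect_equal(nrow(flag_intrageneric(dm_from(sym(0.030001, 2), sp),
                                      t = 0.03)), 0L)
  # t = 0 boundary: only identical heterospecific pairs flagged
  d <- sym(c(0.001, 0, 0.001), 3)
  fl0 <- flag_intrageneric(dm_from(d, c("Xa ya", "Xa za", "Xa wa")), t = 0)
  expect_setequal(fl0$label, c("s01", "s03"))
})

test_that("a single divergent conspecific is the one flagged", {
  # 4 tight sequences plus one outlier at ~9% from all
  n <- 5
  d <- matrix(0.01, n, n); diag(d) <- 0
  d[5, ] <- 0.09; d[, 5] <- 0.09; d[5, 5] <- 0
  fl <- flag_intraspecific(dm_from(d, rep("Xa ya", n)), t = 0.03)
  expect_equal(fl$label, "s05")
  expect_equal(fl$d, 0.09, tolerance = 1e-9)
  expect_equal(fl$threshold, 0.03)
  # all pairwise below t -> nothing flagged
  tight <- matrix(0.01, n, n); diag(tight) <- 0
  expect_equal(nrow(flag_intraspecific(dm_from(tight, rep("Xa ya", n)))), 0L)
})

test_that("the minority cluster is flagged when a species splits in two", {
  n <- 8
  d <- matrix(0.08, n, n)
  d[1:6, 1:6] <- 0.01
  d[7:8, 7:8] <- 0.01
  diag(d) <- 0
  fl <- flag_intraspecific(dm_from(d, rep("Xa ya", n)), t = 0.03)
  expect_setequal(fl$label, c("s07", "s08"))
  # evidence points at the nearest conspecific (the cluster mate)
  expect_equal(fl$d, c(0.01, 0.01))
  # equal-size tie: the cluster holding the lexicographically smallest
  # label survives
  d2 <- matrix(0.08, 4, 4)
  d2[1:2, 1:2] <- 0.01; d2[3:4, 3:4] <- 0.01; diag(d2) <- 0
  fl2 <- flag_intraspecific(dm_from(d2, rep("Xa ya", 4)), t = 0.03)
  expect_setequal(fl2$label, c("s03", "s04"))
})

test_that("single sequences and undefined distances are unassessable", {
  fl <- flag_intraspecific(dm_from(matrix(0, 1, 1), "Xa ya"))
  expect_equal(nrow(fl), 0L)
  expect_equal(attr(fl, "unassessable"), "s01")
  # a sequence with no defined distance is neither accepted nor flagged
  d <- sym(0.01, 3)
  dmx <- dm_from(d, rep("Xa ya", 3))
  dmx$d[3, 1:2] <- NA; dmx$d[1:2, 3] <- NA
  fl2 <- flag_intraspecific(dmx, t = 0.03)
  expect_equal(nrow(fl2), 0L)
  expect_equal(attr(fl2, "unassessable"), "s03")
})

test_that("a mislabeled sequence close to another species flags the pair", {
  # species A cluster (4), species B cluster (3), one A sequence at 0.5%
  # from B's cluster
  n <- 8
  sp <- c(rep("Xa ya", 4), rep("Xa za", 3), "Xa ya")
  d <- matrix(0.10, n, n)
  d[1:4, 1:4] <- 0.01
  d[5:7, 5:7] <- 0.01
  d[8, 5:7] <- 0.005; d[5:7, 8] <- 0.005
  diag(d) <- 0
  fl <- flag_intrageneric(dm_from(d, sp), t = 0.03)
  # the intruder and its nearest heterospecific partners are flagged
  expect_true("s08" %in% fl$label)
  expect_true(all(c("s05", "s06", "s07") %in% fl$label))
  expect_false(any(c("s01", "s02", "s03", "s04") %in% fl$label))
  expect_equal(fl$d[fl$label == "s08"], 0.005)
  # two well-separated species -> no flags
  d2 <- matrix(0.08, 4, 4); d2[1:2, 1:2] <- 0.01; d2[3:4, 3:4] <- 0.01
  diag(d2) <- 0
  expect_equal(nrow(flag_intrageneric(dm_from(d2, rep(c("Xa ya", "Xa za"),
                                                      each = 2)))), 0L)
})

test_that("no sequence is both accepted and flagged by the same rule", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sym(runif(n * (n - 1) / 2, 0, 0.12), n)
    dmx <- dm_from(d, rep("Xa ya", n))
    fl <- flag_intraspecific(dmx, t = 0.03)
    expect_false(any(duplicated(fl$label)))
    accepted <- setdiff(dmx$labels, c(fl$label, attr(fl, "unassessable")))
    expect_length(intersect(accepted, fl$label), 0L)
    expect_equal(length(accepted) + nrow(fl) +
                   length(attr(fl, "unassessable")), n)
  }
})

test_that("raising the threshold shrinks one screen and grows the other", {
  set.seed(62)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    d <- sym(runif(n * (n - 1) / 2, 0, 0.15), n)
    sp <- sample(paste("Xa", c("ya", "za", "wa")), n, TRUE)
    t1 <- runif(1, 0.01, 0.06); t2 <- t1 + runif(1, 0.005, 0.06)
    f1 <- flag_intraspecific(dm_from(d, rep("Xa ya", n)), t1)
    f2 <- flag_intraspecific(dm_from(d, rep("Xa ya", n)), t2)
    expect_lte(nrow(f2), nrow(f1))
    g1 <- flag_intrageneric(dm_from(d, sp), t1)
    g2 <- flag_intrageneric(dm_from(d, sp), t2)
    expect_true(all(g1$label %in% g2$label))
  }
})

test_that("the conflict report aggregates categories with annotations open", {
  empty <- build_conflict_report()
  expect_equal(nrow(empty$report), 0L)
  fl <- rbind(
    flag_intraspecific(dm_from({d <- matrix(0.09, 2, 2); diag(d) <- 0; d},
                               rep("Xa ya", 2),
                               c("Xa_ya_A1", "Xa_ya_A2")), t = 0.03),
    flag_intrageneric(dm_from(sym(0.01, 2), c("Xa ya", "Xa za"),
                              c("Xa_ya_B1", "Xa_za_B2")), t = 0.03))
  rep <- build_conflict_report(
    flags = fl,
    mapping_failures = data.frame(accession = "M1", species = "Xa ya"),
    non_binomials = data.frame(accession = "U1", raw_name = "Xa sp."),
    duplicates = data.frame(accession = "NC_000001", reason = "refseq_duplicate",
                            partner = "A9"))
  expect_equal(sum(rep$counts$n), nrow(rep$report))
  expect_setequal(rep$counts$category,
                  c("intraspecific_divergent", "intrageneric_similar",
                    "mapping_failure", "non_binomial", "duplicate"))
  expect_true(all(rep$report$verdict == ""))
  expect_true(all(c("rationale", "reference") %in% names(rep$report)))
  # divergence evidence is carried in percent with the threshold
  dd <- rep$report[rep$report$category == "intraspecific_divergent", ]
  expect_equal(dd$d_percent, 9)
  expect_equal(dd$threshold_percent, 3)
  # determinism: same inputs, byte-identical report
  rep2 <- build_conflict_report(
    flags = fl,
    mapping_failures = data.frame(accession = "M1", species = "Xa ya"),
    non_binomials = data.frame(accession = "U1", raw_name = "Xa sp."),
    duplicates = data.frame(accession = "NC_000001", reason = "refseq_duplicate",
                            partner = "A9"))
  expect_identical(rep, rep2)
})
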