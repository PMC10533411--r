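# brute-force maximum matching over all k! permutations (oracle for k <= 6)
brute_force_matched <- function(contingency) {
  k <- nrow(contingency)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(k))) {
    best <- max(best, sum(contingency[cbind(seq_len(k), p)]))
  }
  best
}

mk_run <- function(id, classes, categories = NULL, k = NULL) {
  cls <- unique(classes)
  if (is.null(k)) k <- max(3L, length(cls))
  all_cls <- as.character(seq_len(k))
  if (is.null(categories)) {
    categories <- stats::setNames(rep("swapped", k), all_cls)
  }
  classification_run(id, stats::setNames(as.character(classes),
                                         sprintf("p%03d", seq_along(classes))),
                     categories)
}

test_that("category fractions count non-junk particles correctly", {
  cats <- c("1" = "non_swapped", "2" = "swapped", "3" = "junk")
  run <- mk_run("r1", c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2), cats)
  expect_equal(category_fraction(run, "non_swapped"), 0.3)
  expect_equal(category_fraction(run, "swapped"), 0.7)
  # junk particles drop out of the denominator
  run2 <- mk_run("r2", c(1, 1, 2, 2, 3, 3, 3, 3), cats)
  expect_equal(category_fraction(run2, "non_swapped"), 0.5)
  # all-junk: empty denominator errors
  all_junk <- mk_run("r3", c(3, 3, 3),
                     c("1" = "swapped", "2" = "swapped", "3" = "junk"))
  expect_error(category_fraction(all_junk), "non-junk")
})

test_that("category fraction is invariant to splitting a class", {
  set.seed(1)
  n <- 500
  cls <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  cats <- c(a = "swapped", b = "swapped", c = "non_swapped")
  r1 <- classification_run("whole", stats::setNames(cls, sprintf("p%04d", 1:n)), cats)
  # split class "a" into "a1"/"a2" of the same category
  cls2 <- cls
  cls2[cls == "a"] <- sample(c("a1", "a2"), sum(cls == "a"), replace = TRUE)
  cats2 <- c(a1 = "swapped", a2 = "swapped", b = "swapped", c = "non_swapped")
  r2 <- classification_run("split", stats::setNames(cls2, sprintf("p%04d", 1:n)), cats2)
  expect_equal(category_fraction(r1, "non_swapped"),
               category_fraction(r2, "non_swapped"))
})

test_that("planted fractions are recovered within the binomial bound", {
  set.seed(42)
  n <- 1000
  planted <- 0.2
  is_ns <- runif(n) < planted
  cls <- ifelse(is_ns, "n1", sample(c("s1", "s2"), n, replace = TRUE))
  run <- classification_run("planted", stats::setNames(cls, sprintf("p%04d", 1:n)),
                            c(n1 = "non_swapped", s1 = "swapped", s2 = "swapped"))
  expect_lt(abs(category_fraction(run, "non_swapped") - planted),
            3 * sqrt(0.2 * 0.8 / n))
})

test_that("matched fraction: permutation invariance and the hand-worked 2x2 case", {
  set.seed(7)
  cls <- sample(1:4, 200, replace = TRUE)
  ra <- mk_run("a", cls, k = 4)
  # permuted class ids => perfect co-migration
  perm <- c("1" = "3", "2" = "4", "3" = "1", "4" = "2")
  rb <- mk_run("b", perm[as.character(cls)], k = 4)
  cm <- comigration_matched_fraction(ra, rb)
  expect_equal(cm$matched_fraction, 1.0)
  # symmetry
  expect_equal(comigration_matched_fraction(rb, ra)$matched_fraction, 1.0)

  # contingency [[2,1],[0,3]] (padded with an empty third class to satisfy
  # k >= 3): optimal matching 1->1, 2->2, matched fraction 5/6
  la <- c(1, 1, 1, 2, 2, 2)
  lb <- c(1, 1, 2, 2, 2, 2)
  ra2 <- mk_run("a2", la, k = 3)
  rb2 <- mk_run("b2", lb, k = 3)
  cm2 <- comigration_matched_fraction(ra2, rb2)
  expect_equal(cm2$matched_fraction, 5 / 6)
})

test_that("matched fraction errors on mismatched particle sets or k", {
  ra <- mk_run("a", c(1, 2, 3, 1, 2, 3))
  rb <- mk_run("b", c(1, 2, 3, 1, 2, 3, 1))
  expect_error(comigration_matched_fraction(ra, rb), "different particle sets")
  rc <- mk_run("c", c(1, 2, 3, 4, 1, 2), k = 4)
  expect_error(comigration_matched_fraction(ra, rc), "different numbers of classes")
})

test_that("Hungarian matching equals brute force for k <= 6", {
  set.seed(123)
  for (rep_i in 1:60) {
    k <- sample(3:6, 1)
    n <- sample(c(20, 60, 200), 1)
    la <- sample(seq_len(k), n, replace = TRUE)
    lb <- sample(seq_len(k), n, replace = TRUE)
    ra <- mk_run("a", la, k = k)
    rb <- mk_run("b", lb, k = k)
    cm <- comigration_matched_fraction(ra, rb)
    tab <- unclass(table(factor(la, levels = 1:k), factor(lb, levels = 1:k)))
    expect_equal(cm$matched_fraction, brute_force_matched(tab) / n)
  }
})

test_that("independent uniform labelings co-migrate at ~1/k", {
  set.seed(5)
  k <- 5; n <- 10000
  ra <- mk_run("a", sample(1:k, n, replace = TRUE), k = k)
  rb <- mk_run("b", sample(1:k, n, replace = TRUE), k = k)
  cm <- comigration_matched_fraction(ra, rb)
  expect_lt(abs(cm$matched_fraction - 1 / k), 0.03)
})

test_that("consensus summary matches the hand computation", {
  # three perfectly co-migrating runs with fractions 0.20, 0.25, 0.30
  mk_frac_run <- function(id, frac, n = 100) {
    n_ns <- round(frac * n)
    cls <- c(rep("n1", n_ns), rep(c("s1", "s2"), length.out = n - n_ns))
    classification_run(id, stats::setNames(cls, sprintf("p%04d", 1:n)),
                       c(n1 = "non_swapped", s1 = "swapped", s2 = "swapped"))
  }
  # identical particle order => co-migration is high between all pairs
  runs <- list(mk_frac_run("r1", 0.20), mk_frac_run("r2", 0.25),
               mk_frac_run("r3", 0.30))
  sm <- summarize_consensus(runs, category = "non_swapped", k_range = c(3, 20))
  expect_equal(sm$n, 3L)
  expect_equal(sm$mean, 0.25)
  expect_equal(sm$sem, 0.05 / sqrt(3), tolerance = 1e-9)
  expect_equal(sm$sem, 0.0289, tolerance = 1e-2)

  # identical runs repeated: mean = common fraction, sem = 0
  runs5 <- lapply(1:5, function(i) mk_frac_run(paste0("q", i), 0.2))
  sm5 <- summarize_consensus(runs5, category = "non_swapped", k_range = c(3, 20))
  expect_equal(sm5$mean, 0.2)
  expect_equal(sm5$sem, 0)
  expect_equal(sm5$n, 5L)

  # fewer than 2 in-range runs errors
  expect_error(summarize_consensus(runs[1], k_range = c(3, 20)), ">= 2 runs")
})

test_that("inconsistent runs are excluded by the co-migration screen", {
  set.seed(11)
  n <- 300
  base_cls <- sample(c("n1", "s1", "s2"), n, replace = TRUE,
                     prob = c(0.2, 0.4, 0.4))
  cats <- c(n1 = "non_swapped", s1 = "swapped", s2 = "swapped")
  ids <- sprintf("p%04d", 1:n)
  stable <- lapply(1:3, function(i) {
    classification_run(paste0("good", i), stats::setNames(base_cls, ids), cats)
  })
  scrambled <- classification_run("bad", stats::setNames(
    sample(c("n1", "s1", "s2"), n, replace = TRUE), ids), cats)
  sm <- summarize_consensus(c(stable, list(scrambled)),
                            category = "non_swapped", k_range = c(3, 20),
                            consistency_threshold = 0.9)
  expect_equal(sort(sm$consistent_runs), c("good1", "good2", "good3"))
  expect_equal(sm$n, 3L)
})

test_that("classification CSV round trip reproduces runs", {
  labels_path <- withr::local_tempfile(fileext = ".csv")
  cats_path <- withr::local_tempfile(fileext = ".csv")
  lab <- rbind(
    data.frame(particle_id = sprintf("p%02d", 1:10), run_id = "r1",
               class_id = rep(c("c1", "c2", "c3"), length.out = 10)),
    data.frame(particle_id = sprintf("p%02d", 1:10), run_id = "r2",
               class_id = rep(c("c3", "c1", "c2"), length.out = 10)))
  cats <- expand.grid(run_id = c("r1", "r2"), class_id = c("c1", "c2", "c3"),
                      stringsAsFactors = FALSE)
  cats$category <- ifelse(cats$class_id == "c1", "non_swapped", "swapped")
  utils::write.csv(lab, labels_path, row.names = FALSE)
  utils::write.csv(cats, cats_path, row.names = FALSE)
  runs <- read_classification_runs(labels_path, cats_path)
  expect_named(runs, c("r1", "r2"))
  expect_equal(runs$r1$k, 3L)
  expect_equal(category_fraction(runs$r1, "non_swapped"), 0.4)
  # r2 is r1 with permuted class ids: perfect co-migration
  expect_equal(comigration_matched_fraction(runs$r1, runs$r2)$matched_fraction, 1)
})
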