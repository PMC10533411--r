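# Consensus quantification of particle classifications: category fractions
# (swapped / non-swapped / junk), co-migrating particle subsets between runs
# with the same number of classes, and mean +/- s.e. over consistent runs.

#' Construct a classification run
#'
#' One repeat of a particle classification: a particle -> class labelling
#' plus a per-class category annotation. Category calls (swapped,
#' non-swapped, junk) are user input: in practice they come from visual
#' inspection of class maps and cannot be automated here.
#'
#' @param run_id Run identifier.
#' @param labels Named character/integer vector mapping particle id ->
#'   class id, or a data frame with columns `particle_id`, `class_id`.
#' @param class_categories Named character vector mapping class id ->
#'   `"swapped"`, `"non_swapped"` or `"junk"`.
#' @return Object of class `classification_run` with fields `run_id`, `k`,
#'   `labels`, `class_categories`.
#' @export
classification_run <- function(run_id, labels, class_categories) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("particle_id", "class_id") %in% names(labels)))
    lab <- as.character(labels$class_id)
    names(lab) <- as.character(labels$particle_id)
    labels <- lab
  } else {
    labels <- stats::setNames(as.character(labels), names(labels))
  }
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    stop("labels must be uniquely keyed by particle id")
  }
  class_categories <- stats::setNames(as.character(class_categories),
                                      names(class_categories))
  bad_cat <- setdiff(unique(class_categories), c("swapped", "non_swapped", "junk"))
  if (length(bad_cat)) stop("unknown categories: ", paste(bad_cat, collapse = ", "))
  uncat <- setdiff(unique(labels), names(class_categories))
  if (length(uncat)) {
    stop("run '", run_id, "': classes without a category annotation: ",
         paste(uncat, collapse = ", "))
  }
  k <- length(class_categories)
  if (k < 3L) stop("a classification run needs k >= 3 classes")
  structure(list(run_id = as.character(run_id), k = k, labels = labels,
                 class_categories = class_categories),
            class = "classification_run")
}

#' @export
print.classification_run <- function(x, ...) {
  cat("<classification_run> ", x$run_id, ": ", length(x$labels),
      " particles in k = ", x$k, " classes\n", sep = "")
  invisible(x)
}

#' Fraction of particles in one category
#'
#' Particles in classes of the requested category, divided by all particles
#' in non-junk classes.
#'
#' @param run A [classification_run()].
#' @param category `"swapped"` or `"non_swapped"`.
#' @return Fraction in [0, 1].
#' @export
category_fraction <- function(run, category = c("non_swapped", "swapped")) {
  category <- match.arg(category)
  cat_of <- run$class_categories[run$labels]
  n_nonjunk <- sum(cat_of != "junk")
  if (n_nonjunk == 0L) stop("run '", run$run_id, "': no particles in non-junk classes")
  sum(cat_of == category) / n_nonjunk
}

# Exact Hungarian algorithm (O(n^3), shortest augmenting paths with
# potentials) for a square min-cost assignment. Returns for each column the
# matched row. Deterministic.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[2:(n + 1L)]  # row matched to each column
}

# maximum-weight one-to-one matching of a square non-negative weight matrix
solve_max_assignment <- function(w) {
  cost <- max(w) - w
  col_to_row <- hungarian_min(cost)
  data.frame(row = col_to_row, col = seq_len(ncol(w)))
}

#' Co-migrating particle fraction between two classification runs
#'
#' Builds the k x k contingency matrix of shared particles between the class
#' labellings of two runs with the same particle set and the same number of
#' classes, solves the maximum-weight one-to-one class matching exactly
#' (Hungarian algorithm), and reports the fraction of particles that sit in
#' matched cells. Invariant to class-id permutation and symmetric in its two
#' arguments.
#'
#' @param run_a,run_b [classification_run()] objects over the same particles
#'   and equal k.
#' @return List with `matched_fraction` in [0, 1] and `matching` (data frame
#'   `class_a`, `class_b`, `shared`).
#' @export
comigration_matched_fraction <- function(run_a, run_b) {
  if (run_a$k != run_b$k) {
    stop("runs have different numbers of classes: ", run_a$k, " vs ", run_b$k)
  }
  pa <- names(run_a$labels); pb <- names(run_b$labels)
  if (!setequal(pa, pb) || length(pa) != length(pb)) {
    stop("runs are over different particle sets (symmetric difference: ",
         length(union(setdiff(pa, pb), setdiff(pb, pa))), " particles)")
  }
  classes_a <- sort(names(run_a$class_categories))
  classes_b <- sort(names(run_b$class_categories))
  la <- factor(run_a$labels[pa], levels = classes_a)
  lb <- factor(run_b$labels[pa], levels = classes_b)
  contingency <- unclass(table(la, lb))
  m <- solve_max_assignment(contingency)
  shared <- contingency[cbind(m$row, m$col)]
  list(matched_fraction = sum(shared) / length(pa),
       matching = data.frame(class_a = classes_a[m$row],
                             class_b = classes_b[m$col],
                             shared = shared, stringsAsFactors = FALSE))
}

#' Consensus summary of category fractions across runs
#'
#' Runs whose class count falls inside `k_range` are screened for
#' consistency: a run is consistent when its co-migrating matched fraction
#' exceeds `consistency_threshold` against at least half of the other
#' in-range runs with the same k. The summary reports the mean and standard
#' error (sample SD / sqrt(n), SD with the n-1 denominator) of the category
#' fraction over the consistent runs, with n the number of consistent runs.
#'
#' @param runs List of [classification_run()] objects.
#' @param category Category to summarize (default `"non_swapped"`).
#' @param k_range Inclusive class-count window, default `c(6, 20)`.
#' @param consistency_threshold Matched-fraction threshold, default 0.6.
#' @return Object of class `consensus_summary`: `per_run` (run_id, k,
#'   fraction, consistent), `comigration` (pairwise matched fractions),
#'   `consistent_runs`, `mean`, `sem`, `n`.
#' @export
summarize_consensus <- function(runs, category = c("non_swapped", "swapped"),
                                k_range = c(6, 20),
                                consistency_threshold = 0.6) {
  category <- match.arg(category)
  ks <- vapply(runs, function(r) r$k, numeric(1))
  in_range <- which(ks >= k_range[1] & ks <= k_range[2])
  if (length(in_range) < 2L) stop("need >= 2 runs with k in [",
                                  k_range[1], ", ", k_range[2], "]")
  runs_in <- runs[in_range]
  ids <- vapply(runs_in, function(r) r$run_id, character(1))
  ks_in <- ks[in_range]
  pair_rows <- list()
  n_above <- integer(length(runs_in))
  n_pairs <- integer(length(runs_in))
  for (i in seq_along(runs_in)) {
    for (j in seq_along(runs_in)) {
      if (j <= i || ks_in[i] != ks_in[j]) next
      mf <- comigration_matched_fraction(runs_in[[i]], runs_in[[j]])$matched_fraction
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        run_a = ids[i], run_b = ids[j], k = ks_in[i],
        matched_fraction = mf, stringsAsFactors = FALSE)
      n_pairs[c(i, j)] <- n_pairs[c(i, j)] + 1L
      if (mf > consistency_threshold) n_above[c(i, j)] <- n_above[c(i, j)] + 1L
    }
  }
  consistent <- n_pairs > 0L & n_above >= n_pairs / 2
  if (sum(consistent) < 2L) {
    stop("fewer than 2 consistent runs: standard error undefined")
  }
  fractions <- vapply(runs_in, category_fraction, numeric(1), category = category)
  fr <- fractions[consistent]
  summary <- structure(list(
    category = category,
    per_run = data.frame(run_id = ids, k = ks_in, fraction = fractions,
                         consistent = consistent, stringsAsFactors = FALSE),
    comigration = do.call(rbind, pair_rows),
    consistent_runs = ids[consistent],
    mean = mean(fr),
    sem = stats::sd(fr) / sqrt(length(fr)),
    n = length(fr)), class = "consensus_summary")
  summary
}

#' @export
print.consensus_summary <- function(x, ...) {
  cat("<consensus_summary> ", x$category, " fraction = ",
      sprintf("%.4f +/- %.4f", x$mean, x$sem),
      " (mean +/- s.e., n = ", x$n, " consistent runs)\n", sep = "")
  invisible(x)
}

#' Read classification runs from CSV tables
#'
#' `labels_path` has one row per particle per run (columns `particle_id`,
#' `run_id`, `class_id`); `categories_path` annotates classes (columns
#' `run_id`, `class_id`, `category`).
#'
#' @param labels_path,categories_path CSV file paths.
#' @return List of [classification_run()] objects, one per run id.
#' @export
read_classification_runs <- function(labels_path, categories_path) {
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  cat_tbl <- utils::read.csv(categories_path, stringsAsFactors = FALSE)
  stopifnot(all(c("particle_id", "run_id", "class_id") %in% names(lab)),
            all(c("run_id", "class_id", "category") %in% names(cat_tbl)))
  run_ids <- unique(lab$run_id)
  out <- lapply(run_ids, function(rid) {
    li <- lab[lab$run_id == rid, ]
    ci <- cat_tbl[cat_tbl$run_id == rid, ]
    classification_run(rid, li[, c("particle_id", "class_id")],
                       stats::setNames(ci$category, as.character(ci$class_id)))
  })
  names(out) <- run_ids
  out
}
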