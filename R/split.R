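#' Covariate-balanced train/test split
#'
#' Draws many random partitions of the cohort and keeps the one whose
#' covariates are best balanced between the two sides. Balance of each
#' categorical variable (gender, complication count, surgery type) is
#' scored with an (uncorrected) chi-square test of side vs category;
#' balance of each numerical variable (age, LOS) with a two-sample
#' Kolmogorov-Smirnov test. The candidate with the largest product of
#' p-values wins.
#'
#' @param cohort list of patient records or a [cohort_frame()].
#' @param categorical_vars,numerical_vars column names to balance.
#' @param fraction training fraction; the train size is
#'   `floor(fraction * n)`.
#' @param n_candidates number of random partitions to score.
#' @param seed integer seed making the search reproducible.
#' @return a `split_result`: `train_ids`, `test_ids`, `balance_score`
#'   (product of p-values), `per_variable_p`.
#' @export
balanced_split <- function(cohort,
                           categorical_vars = c("gender", "n_complications",
                                                "surgery_type"),
                           numerical_vars = c("age", "los"),
                           fraction = 2 / 3,
                           n_candidates = 10000L,
                           seed = 1L) {
  df <- if (is.data.frame(cohort)) cohort else cohort_frame(cohort)
  if (n_candidates < 1L) stop("n_candidates must be >= 1", call. = FALSE)
  missing_vars <- setdiff(c(categorical_vars, numerical_vars), names(df))
  if (length(missing_vars)) {
    stop("variables absent from cohort: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  n_train <- floor(fraction * n)
  if (n_train < 1L || n_train > n) stop("fraction yields an empty side", call. = FALSE)
  set.seed(seed)
  cat_vals <- lapply(categorical_vars, function(v) as.character(df[[v]]))
  names(cat_vals) <- categorical_vars
  num_vals <- lapply(numerical_vars, function(v) as.numeric(df[[v]]))
  names(num_vals) <- numerical_vars

  best_score <- -Inf; best_idx <- NULL; best_p <- NULL
  for (i in seq_len(n_candidates)) {
    idx <- sample.int(n, n_train)
    in_train <- logical(n); in_train[idx] <- TRUE
    p <- c(
      vapply(cat_vals, function(v) chisq_p(v, in_train), numeric(1)),
      vapply(num_vals, function(v) ks_p(v[in_train], v[!in_train]), numeric(1))
    )
    score <- prod(p)
    if (score > best_score) {
      best_score <- score; best_idx <- idx; best_p <- p
    }
  }
  structure(list(
    train_ids = df$patient_id[sort(best_idx)],
    test_ids = df$patient_id[sort(setdiff(seq_len(n), best_idx))],
    balance_score = best_score,
    per_variable_p = best_p,
    fraction = fraction, n_candidates = n_candidates, seed = seed
  ), class = "split_result")
}

# chi-square p for a category vector vs a train/test indicator.
# Zero-total categories are dropped; if the statistic is undefined
# (one remaining category, or an empty side) the variable is neutral: p = 1.
chisq_p <- function(values, in_train) {
  tab <- table(values, in_train)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L || any(colSums(tab) == 0)) return(1)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  stats::pchisq(stat, df = (nrow(tab) - 1) * (ncol(tab) - 1), lower.tail = FALSE)
}

# asymptotic two-sample Kolmogorov-Smirnov p-value
ks_p <- function(x, y) {
  suppressWarnings(stats::ks.test(x, y)$p.value)
}

#' Re-score one split
#'
#' Computes the per-variable p-values and balance score of an explicit
#' partition, with the same tests as [balanced_split()]. Useful for
#' verifying the optimality of a search result.
#'
#' @param df a [cohort_frame()].
#' @param train_ids patient ids on the training side.
#' @inheritParams balanced_split
#' @return list with `per_variable_p` and `balance_score`.
#' @export
score_split <- function(df, train_ids,
                        categorical_vars = c("gender", "n_complications",
                                             "surgery_type"),
                        numerical_vars = c("age", "los")) {
  in_train <- df$patient_id %in% train_ids
  p <- c(
    vapply(categorical_vars,
           function(v) chisq_p(as.character(df[[v]]), in_train), numeric(1)),
    vapply(numerical_vars,
           function(v) ks_p(df[[v]][in_train], df[[v]][!in_train]), numeric(1))
  )
  list(per_variable_p = p, balance_score = prod(p))
}

#' Tabulate a split
#'
#' Per-variable counts, percentages and means for the training and test
#' sides, in the layout of a cohort characteristics table.
#'
#' @param result a `split_result`.
#' @param cohort list of patient records or a [cohort_frame()].
#' @return data.frame with columns `variable`, `train`, `test`,
#'   `train_pct`, `test_pct`.
#' @export
split_report <- function(result, cohort) {
  df <- if (is.data.frame(cohort)) cohort else cohort_frame(cohort)
  in_train <- df$patient_id %in% result$train_ids
  if (all(in_train) || !any(in_train)) {
    warning("degenerate split: one side is empty")
  }
  row_count <- function(label, sel) {
    a <- sum(sel & in_train); b <- sum(sel & !in_train)
    tot <- a + b
    data.frame(variable = label, train = a, test = b,
               train_pct = if (tot > 0) 100 * a / tot else NA_real_,
               test_pct = if (tot > 0) 100 * b / tot else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list(row_count("Total patients", rep(TRUE, nrow(df))))
  for (g in sort(unique(df$gender))) {
    lab <- paste0(toupper(substring(g, 1, 1)), substring(g, 2))
    rows <- c(rows, list(row_count(lab, df$gender == g)))
  }
  for (k in sort(unique(df$n_complications))) {
    lab <- sprintf("Patients with %d complication(s)", k)
    rows <- c(rows, list(row_count(lab, df$n_complications == k)))
  }
  for (s in sort(unique(df$surgery_type))) {
    rows <- c(rows, list(row_count(paste("Surgery:", s), df$surgery_type == s)))
  }
  out <- do.call(rbind, rows)
  means <- data.frame(
    variable = c("Age (mean)", "LOS (mean)"),
    train = c(mean(df$age[in_train]), mean(df$los[in_train])),
    test = c(mean(df$age[!in_train]), mean(df$los[!in_train])),
    train_pct = NA_real_, test_pct = NA_real_, stringsAsFactors = FALSE)
  rbind(out, means)
}
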