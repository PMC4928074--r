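#' Group summary: mean, SD, SEM
#'
#' @param values numeric vector, length >= 2.
#' @param label group name.
#' @return a `group_summary`: `label`, `n`, `mean`, `sd` (n-1 denominator),
#'   `sem = sd / sqrt(n)`.
#' @export
summarize_group <- function(values, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a group summary needs n >= 2", call. = FALSE)
  s <- stats::sd(values)
  structure(list(label = label, n = length(values), mean = mean(values),
                 sd = s, sem = s / sqrt(length(values))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g ± %.3g (S.E.M), SD %.3g, n = %d\n",
              if (nzchar(x$label)) x$label else "group",
              x$mean, x$sem, x$sd, x$n))
  invisible(x)
}

#' Two-tailed t-test assuming unequal variances (Welch)
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return a `comparison_result` with the Welch statistic,
#'   Welch-Satterthwaite degrees of freedom and the two-tailed p-value.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(structure(list(test = "welch_t", statistic = 0,
                            df = length(a) + length(b) - 2, p_values = 1,
                            alpha = 0.05),
                       class = "comparison_result"))
    stop("both groups have zero variance but different means; ",
         "a t-test is undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(test = "welch_t",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_values = ht$p.value, alpha = 0.05),
            class = "comparison_result")
}

#' One-way ANOVA with post-hoc Tukey HSD
#'
#' Omnibus F-test across `k >= 2` groups followed by all pairwise
#' comparisons adjusted with Tukey's honestly significant difference
#' (studentized-range distribution; Tukey-Kramer for unbalanced groups).
#'
#' @param groups named list of numeric vectors, each n >= 2.
#' @param alpha significance level recorded in the result.
#' @return a `comparison_result`: `statistic` (F), `df`
#'   `c(between, within)`, `p_values` a symmetric k x k matrix of
#'   Tukey-adjusted pairwise p-values, `p_omnibus`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 0L)),
               levels = names(groups)))
  k <- length(groups)
  # an exactly constant response carries no evidence of group differences;
  # aov would only return round-off noise there
  if (stats::var(df$y) <= 1e-12 * (mean(df$y)^2 + 1)) {
    pmat <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
    return(structure(list(test = "anova_tukey", statistic = 0,
                          df = c(between = k - 1,
                                 within = nrow(df) - k),
                          p_values = pmat, p_omnibus = 1, alpha = alpha),
                     class = "comparison_result"))
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  p_omni <- an[["Pr(>F)"]][1]
  if (is.na(Fv)) { Fv <- 0; p_omni <- 1 }   # zero within-group variance
  tuk <- stats::TukeyHSD(fit)$g
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                                 names(groups)))
  diag(pmat) <- 1
  for (r in rownames(tuk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    p <- tuk[r, "p adj"]
    pmat[pair[1], pair[2]] <- p
    pmat[pair[2], pair[1]] <- p
  }
  structure(list(test = "anova_tukey", statistic = Fv,
                 df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
                 p_values = pmat, p_omnibus = p_omni, alpha = alpha),
            class = "comparison_result")
}

#' Welch t-test from printed summary statistics
#'
#' Lets published tables (n, mean, SEM or SD per group) be re-analyzed
#' without raw data.
#'
#' @param n1,mean1,n2,mean2 group sizes and means.
#' @param sd1,sd2 group SDs; alternatively give `sem1`/`sem2`.
#' @param sem1,sem2 group SEMs (converted via `sd = sem * sqrt(n)`).
#' @return a `comparison_result` as in [welch_t()].
#' @export
welch_t_from_summary <- function(n1, mean1, n2, mean2,
                                 sd1 = NULL, sd2 = NULL,
                                 sem1 = NULL, sem2 = NULL) {
  if (is.null(sd1)) sd1 <- sem1 * sqrt(n1)
  if (is.null(sd2)) sd2 <- sem2 * sqrt(n2)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0, sd1 + sd2 > 0)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  structure(list(test = "welch_t", statistic = t, df = df,
                 p_values = 2 * stats::pt(-abs(t), df), alpha = 0.05),
            class = "comparison_result")
}

#' ANOVA + Tukey HSD from printed summary statistics
#'
#' @param n,means integer/numeric vectors of group sizes and means.
#' @param sds group SDs; alternatively give `sems`.
#' @param sems group SEMs.
#' @param labels group names.
#' @param alpha significance level recorded in the result.
#' @return a `comparison_result` as in [anova_tukey()].
#' @export
anova_tukey_from_summary <- function(n, means, sds = NULL, sems = NULL,
                                     labels = NULL, alpha = 0.05) {
  if (is.null(sds)) sds <- sems * sqrt(n)
  k <- length(n)
  stopifnot(k >= 2, length(means) == k, length(sds) == k, all(n >= 2))
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  N <- sum(n)
  gm <- sum(n * means) / N
  ss_b <- sum(n * (means - gm)^2)
  ss_w <- sum((n - 1) * sds^2)
  df_b <- k - 1; df_w <- N - k
  msw <- ss_w / df_w
  Fv <- if (msw > 0) (ss_b / df_b) / msw else 0
  p_omni <- if (msw > 0) stats::pf(Fv, df_b, df_w, lower.tail = FALSE) else
    as.numeric(ss_b == 0)
  pmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(pmat) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (msw > 0) {
      q <- abs(means[i] - means[j]) /
        sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))   # Tukey-Kramer
      p <- stats::ptukey(q, k, df_w, lower.tail = FALSE)
    } else p <- as.numeric(means[i] == means[j])
    pmat[i, j] <- pmat[j, i] <- p
  }
  structure(list(test = "anova_tukey", statistic = Fv,
                 df = c(between = df_b, within = df_w),
                 p_values = pmat, p_omnibus = p_omni, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$test == "welch_t") {
    cat(sprintf("Welch t = %.3f, df = %.2f, p = %.4g\n",
                x$statistic, x$df, x$p_values))
  } else {
    cat(sprintf("one-way ANOVA F(%d, %d) = %.3f, p = %.4g\n",
                x$df[1], x$df[2], x$statistic, x$p_omnibus))
    cat("Tukey HSD pairwise p-values:\n")
    print(round(x$p_values, 4))
  }
  invisible(x)
}

#' Per-cycle-length restitution comparison across conditions
#'
#' Runs an independent one-way ANOVA with Tukey HSD at every pacing cycle
#' length shared by all conditions and flags pairs significant at `alpha`.
#'
#' @param samples named list (one entry per condition) of named lists keyed
#'   by cycle length, each a numeric vector of per-slice duration values.
#' @param alpha significance level for flagging.
#' @return data.frame with `pcl_ms`, `pair`, `p_value`, `significant`; zero
#'   rows when fewer than two conditions are given.
#' @export
compare_restitution <- function(samples, alpha = 0.05) {
  empty <- data.frame(pcl_ms = numeric(), pair = character(),
                      p_value = numeric(), significant = logical())
  if (length(samples) < 2L) return(empty)
  pcl_sets <- lapply(samples, names)
  shared <- Reduce(intersect, pcl_sets)
  if (!length(shared))
    stop("conditions share no pacing cycle lengths", call. = FALSE)
  if (any(vapply(pcl_sets, function(s) length(setdiff(s, shared)) > 0, TRUE)))
    warning("restricting comparison to shared cycle lengths", call. = FALSE)
  shared <- shared[order(-as.numeric(shared))]
  rows <- list()
  for (pcl in shared) {
    groups <- lapply(samples, function(cond) cond[[pcl]])
    res <- anova_tukey(groups, alpha = alpha)
    pm <- res$p_values
    labs <- rownames(pm)
    for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pcl_ms = as.numeric(pcl),
        pair = paste(labs[i], labs[j], sep = " vs "),
        p_value = pm[i, j], significant = pm[i, j] < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Write summary and comparison tables
#'
#' Writes `group_summaries.csv`, `pairwise_p.csv` (when comparisons are
#' given), `per_pcl_flags.csv` (when a restitution comparison table is
#' given) and a plain-text `run_log.txt` echoing versions and
#' configuration. Reruns with identical inputs produce byte-identical CSV
#' files.
#'
#' @param summaries list of `group_summary` objects with unique labels.
#' @param comparisons optional named list of `comparison_result` objects.
#' @param restitution_flags optional data.frame from
#'   [compare_restitution()].
#' @param out_dir output directory (created if missing).
#' @param config optional list echoed into the run log.
#' @return invisibly, the paths written.
#' @export
write_report <- function(summaries, comparisons = NULL,
                         restitution_flags = NULL, out_dir,
                         config = list()) {
  labs <- vapply(summaries, function(s) s$label, "")
  if (anyDuplicated(labs))
    stop("group labels collide: ", paste(labs[duplicated(labs)],
                                         collapse = ", "), call. = FALSE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character()

  sm <- do.call(rbind, lapply(summaries, function(s)
    data.frame(label = s$label, n = s$n, mean = s$mean, sd = s$sd,
               sem = s$sem)))
  p1 <- file.path(out_dir, "group_summaries.csv")
  utils::write.csv(sm, p1, row.names = FALSE)
  paths <- c(paths, p1)

  if (!is.null(comparisons) && length(comparisons)) {
    rows <- list()
    for (nm in names(comparisons)) {
      cr <- comparisons[[nm]]
      if (cr$test == "welch_t") {
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = nm, test = cr$test, pair = nm,
          statistic = cr$statistic, p_value = cr$p_values)
      } else {
        pm <- cr$p_values
        labs2 <- rownames(pm)
        for (i in seq_len(length(labs2) - 1)) for (j in (i + 1):length(labs2))
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = nm, test = cr$test,
            pair = paste(labs2[i], labs2[j], sep = " vs "),
            statistic = cr$statistic, p_value = pm[i, j])
      }
    }
    p2 <- file.path(out_dir, "pairwise_p.csv")
    utils::write.csv(do.call(rbind, rows), p2, row.names = FALSE)
    paths <- c(paths, p2)
  }

  if (!is.null(restitution_flags) && nrow(restitution_flags)) {
    p3 <- file.path(out_dir, "per_pcl_flags.csv")
    utils::write.csv(restitution_flags, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  lines <- c(
    paste0("R version: ", R.version.string),
    paste0("cardiomap version: ",
           as.character(utils::packageVersion("cardiomap"))),
    "config:",
    if (length(config))
      paste0("  ", names(config), " = ",
             vapply(config, function(v) paste(format(v), collapse = " "),
                    "")) else "  (none)")
  writeLines(lines, log_path)
  invisible(c(paths, log_path))
}
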