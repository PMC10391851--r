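# Group-comparison machinery for the factorial results:
# normality-gated choice between one-way ANOVA and Kruskal-Wallis,
# Bonferroni-adjusted pairwise post-hocs, and report tables in the three
# comparison layouts (across loads, across bone qualities, across
# surgeries). The 16 monitored points of a cell serve as the
# statistical sample; this is pseudo-replication and is flagged in
# every generated report.

#' Choose the omnibus test for a set of samples
#'
#' One-way ANOVA when every group passes a Shapiro-Wilk normality check
#' at `alpha`, otherwise Kruskal-Wallis. Degenerate input (any
#' zero-variance group, or groups too small for the normality check) is
#' an error.
#'
#' @param samples List of >= 2 numeric vectors, each of length >= 3.
#' @param alpha Normality test level, default 0.05.
#' @return `"anova"` or `"kruskal"`, with attribute `shapiro_p`.
#' @export
choose_test <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 1L) < 3))
    stop("each group needs at least 3 values")
  if (any(vapply(samples, stats::sd, 1) == 0))
    stop("zero-variance degenerate input")
  p <- vapply(samples, function(s) stats::shapiro.test(s)$p.value, 1)
  test <- if (all(p > alpha)) "anova" else "kruskal"
  attr(test, "shapiro_p") <- p
  test
}

#' Kruskal-Wallis rank-sum test with exact small-sample p-value
#'
#' Computes the tie-corrected Kruskal-Wallis statistic H. For small
#' samples (number of distinct group assignments at most `exact_limit`)
#' the p-value is the exact permutation tail probability
#' `P(H* >= H)` over all distinct assignments of the pooled values to
#' the group sizes; otherwise the usual chi-square approximation with
#' `g - 1` degrees of freedom is used. The statistic agrees with
#' [stats::kruskal.test()].
#'
#' @param samples List of numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by `exact_limit`.
#' @param exact_limit Maximum number of assignments to enumerate.
#' @return List with `statistic`, `p_value`, `df`, `method`
#'   (`"exact"` or `"chisq"`).
#' @export
kruskal_wallis <- function(samples, exact = NULL, exact_limit = 1e5) {
  stopifnot(is.list(samples), length(samples) >= 2)
  sizes <- vapply(samples, length, 1L)
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(samples), sizes)

  H_of <- function(rr, gg) {
    Ri <- tapply(rr, gg, sum)
    H <- 12 / (N * (N + 1)) * sum(Ri^2 / sizes) - 3 * (N + 1)
    ties <- table(rr)
    corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    if (corr == 0) stop("all observations tied: degenerate input")
    H / corr
  }
  H <- unname(H_of(r, g))

  n_assign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  if (is.null(exact)) exact <- n_assign <= exact_limit
  if (exact && n_assign > 5e6) stop("too many assignments for exact enumeration")

  if (exact) {
    # enumerate all distinct ways to split the pooled ranks into groups
    stats_all <- numeric(0)
    recurse <- function(avail, gi, assign) {
      if (gi == length(sizes)) {
        assign[avail] <- gi
        stats_all[length(stats_all) + 1L] <<- H_of(r, assign)
        return(invisible())
      }
      picks <- utils::combn(avail, sizes[gi], simplify = FALSE)
      for (p in picks) {
        a2 <- assign; a2[p] <- gi
        recurse(setdiff(avail, p), gi + 1L, a2)
      }
    }
    recurse(seq_len(N), 1L, integer(N))
    p_value <- mean(stats_all >= H - 1e-12)
    method <- "exact"
  } else {
    p_value <- stats::pchisq(H, df = length(samples) - 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(statistic = H, p_value = p_value, df = length(samples) - 1,
       method = method)
}

#' Compare groups with omnibus test and pairwise post-hocs
#'
#' Runs the chosen omnibus test and all pairwise comparisons with
#' Bonferroni multiplicity adjustment (pairwise Welch t-tests under
#' ANOVA, pairwise two-group Kruskal-Wallis otherwise, exact for small
#' samples). Significance is flagged at `alpha = 0.05`.
#'
#' @param samples Named list of numeric vectors.
#' @param test `"anova"`, `"kruskal"`, or `NULL` to call [choose_test()].
#' @param alpha Significance level.
#' @return Object of class `comparison_result`: `test`, omnibus
#'   `statistic` and `p_value`, and a `pairwise` data frame with raw and
#'   Bonferroni-adjusted p-values.
#' @export
compare_groups <- function(samples, test = NULL, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  if (is.null(test)) test <- choose_test(samples)
  test <- match.arg(as.character(test), c("anova", "kruskal"))

  if (test == "anova") {
    dat <- data.frame(y = unlist(samples, use.names = FALSE),
                      grp = factor(rep(names(samples),
                                       vapply(samples, length, 1L))))
    fit <- stats::aov(y ~ grp, data = dat)
    tab <- summary(fit)[[1]]
    statistic <- tab[["F value"]][1]
    p_value <- tab[["Pr(>F)"]][1]
  } else {
    kw <- kruskal_wallis(samples)
    statistic <- kw$statistic
    p_value <- kw$p_value
  }

  pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- samples[[pr[1]]]; b <- samples[[pr[2]]]
    p_raw <- if (test == "anova") {
      stats::t.test(a, b)$p.value
    } else {
      kruskal_wallis(list(a, b))$p_value
    }
    data.frame(group1 = pr[1], group2 = pr[2], p_raw = p_raw,
               p_adj = min(1, p_raw * m))
  }))
  pw$significant <- pw$p_adj < alpha
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 significant = p_value < alpha, alpha = alpha,
                 adjustment = "bonferroni", pairwise = pw),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s omnibus: statistic = %.4g, p = %.4g%s\n",
              if (x$test == "anova") "One-way ANOVA" else "Kruskal-Wallis",
              x$statistic, x$p_value, if (x$significant) " *" else ""))
  print(x$pairwise, row.names = FALSE, ...)
  invisible(x)
}

# assemble one comparison block: groups of monitored-point values from a
# grid, omnibus + pairwise rows
.compare_block <- function(samples, labels) {
  cr <- tryCatch(compare_groups(samples), error = identity)
  if (inherits(cr, "error")) {
    return(data.frame(comparison = paste(names(samples), collapse = ":"),
                      test = NA, statistic = NA_real_, p_value = NA_real_,
                      p_adj = NA_real_, significant = NA,
                      note = conditionMessage(cr)))
  }
  data.frame(comparison = paste(cr$pairwise$group1, cr$pairwise$group2,
                                sep = ":"),
             test = cr$test, statistic = cr$statistic,
             p_value = cr$p_value, p_adj = cr$pairwise$p_adj,
             significant = cr$pairwise$significant, note = "")
}

.cell_points <- function(grid, sg, bq, ld, channel) {
  key <- paste(sg, bq, ld, sep = ":")
  cs <- grid$cases[[key]]
  if (is.null(cs)) return(NULL)
  if (channel == "stress") cs$points$stress$von_mises
  else cs$points$displacement$displacement_um
}

#' Render report tables from a completed grid
#'
#' Builds the three comparison layouts on the monitored-point samples:
#' across loads within surgery x quality, across bone qualities within
#' surgery x load, and across surgeries within quality x load, for both
#' the Von Mises stress and displacement channels, plus the cell summary
#' table (mean +/- SD over the 16 monitored points per cell).
#'
#' @param grid An `fsu_grid` from [run_grid()].
#' @return List of data frames: `cells`, `by_load`, `by_quality`,
#'   `by_surgery`; class `fsu_report`.
#' @export
render_tables <- function(grid) {
  stopifnot(inherits(grid, "fsu_grid"))
  channels <- c("stress", "displacement")
  by_load <- list(); by_quality <- list(); by_surgery <- list()
  for (ch in channels) {
    for (sg in grid$surgeries) for (bq in grid$qualities) {
      samples <- lapply(grid$loads, function(ld)
        .cell_points(grid, sg, bq, ld, ch))
      names(samples) <- paste0(grid$loads, "N")
      if (any(vapply(samples, is.null, TRUE))) next
      blk <- .compare_block(samples)
      blk <- cbind(data.frame(channel = ch, surgery = sg, bone_quality = bq),
                   blk)
      by_load[[length(by_load) + 1L]] <- blk
    }
    for (sg in grid$surgeries) for (ld in grid$loads) {
      samples <- lapply(grid$qualities, function(bq)
        .cell_points(grid, sg, bq, ld, ch))
      names(samples) <- grid$qualities
      if (any(vapply(samples, is.null, TRUE))) next
      blk <- .compare_block(samples)
      blk <- cbind(data.frame(channel = ch, surgery = sg, load_N = ld), blk)
      by_quality[[length(by_quality) + 1L]] <- blk
    }
    for (bq in grid$qualities) for (ld in grid$loads) {
      samples <- lapply(grid$surgeries, function(sg)
        .cell_points(grid, sg, bq, ld, ch))
      names(samples) <- grid$surgeries
      if (any(vapply(samples, is.null, TRUE))) next
      blk <- .compare_block(samples)
      blk <- cbind(data.frame(channel = ch, bone_quality = bq, load_N = ld),
                   blk)
      by_surgery[[length(by_surgery) + 1L]] <- blk
    }
  }
  structure(list(cells = grid$summary,
                 by_load = do.call(rbind, by_load),
                 by_quality = do.call(rbind, by_quality),
                 by_surgery = do.call(rbind, by_surgery)),
            class = "fsu_report")
}

.REPORT_FOOTER <- paste(
  "Caveats:",
  "(1) The 16 monitored points of a cell are spatial samples from one",
  "deterministic field, not independent replicates; all p-values below are",
  "descriptive (pseudo-replication), not inferential.",
  "(2) Absolute stress/displacement magnitudes and the statistic/p values of",
  "any patient-derived model depend on the individual CT geometry and its",
  "meshing and are NOT reproduced by this idealized parametric geometry;",
  "only the qualitative orderings across surgery, bone quality and load are",
  "comparable (and are covered by the property-based trend checks).",
  sep = "\n")

#' Write report files for a grid
#'
#' Writes `table2_analog.csv` (cell summaries), `table3_analog.csv`
#' (across loads), `table4_analog.csv` (across bone qualities),
#' `table5_analog.csv` (across surgeries) and a `report.md` with the
#' mandatory caveat footer on pseudo-replication and on the
#' non-reproducibility of patient-specific magnitudes.
#'
#' @param report An `fsu_report` from [render_tables()] (or an
#'   `fsu_grid`, rendered on the fly).
#' @param dir Output directory, created if needed.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  if (inherits(report, "fsu_grid")) report <- render_tables(report)
  stopifnot(inherits(report, "fsu_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table2 = file.path(dir, "table2_analog.csv"),
    table3 = file.path(dir, "table3_analog.csv"),
    table4 = file.path(dir, "table4_analog.csv"),
    table5 = file.path(dir, "table5_analog.csv"),
    report = file.path(dir, "report.md"))
  utils::write.csv(report$cells, paths["table2"], row.names = FALSE)
  utils::write.csv(report$by_load, paths["table3"], row.names = FALSE)
  utils::write.csv(report$by_quality, paths["table4"], row.names = FALSE)
  utils::write.csv(report$by_surgery, paths["table5"], row.names = FALSE)

  fmt_cells <- report$cells
  fmt <- function(df) paste(utils::capture.output(print(df, row.names = FALSE)),
                            collapse = "\n")
  md <- c(
    "# Static FE comparison of anterior cervical constructs",
    "", "## Cell summaries (mean +/- SD over 16 monitored points)", "",
    "```", fmt(fmt_cells), "```",
    "", "## Comparisons across loads (within surgery x bone quality)", "",
    "```", fmt(report$by_load), "```",
    "", "## Comparisons across bone qualities (within surgery x load)", "",
    "```", fmt(report$by_quality), "```",
    "", "## Comparisons across surgeries (within bone quality x load)", "",
    "```", fmt(report$by_surgery), "```",
    "", "---", "", .REPORT_FOOTER, "")
  writeLines(md, paths["report"])
  invisible(paths)
}
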