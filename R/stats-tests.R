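# Group comparison and contingency tests used throughout subtype
# characterization (VAF by subtype, enrichment by subtype, Table-1-style
# clinical summaries).

#' Compare a numeric variable across groups
#'
#' Two-group comparisons use the Wilcoxon rank-sum test: exact by complete
#' enumeration of rank splits (average-rank ties) when the combined n is at
#' most 12, and the normal approximation with tie correction otherwise.
#' Three or more groups use Kruskal-Wallis or one-way ANOVA.
#'
#' @param values numeric vector.
#' @param labels group labels, same length.
#' @param test `"wilcoxon"` (2 groups only), `"kruskal"`, or `"anova"`.
#' @param exact_max maximum combined n for exact Wilcoxon enumeration.
#' @return list with `statistic`, `p`, `method`.
#' @export
group_compare <- function(values, labels,
                          test = c("wilcoxon", "kruskal", "anova"),
                          exact_max = 12) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep])
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  if (test == "wilcoxon" && nlevels(labels) != 2)
    stop("wilcoxon requires exactly 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("all values tied; p = 1", call. = FALSE)
    return(list(statistic = 0, p = 1, method = paste0(test, " (degenerate)")))
  }
  if (test == "wilcoxon") {
    wilcoxon_ranksum(values[labels == levels(labels)[1]],
                     values[labels == levels(labels)[2]],
                     exact_max = exact_max)
  } else if (test == "kruskal") {
    k <- stats::kruskal.test(values, labels)
    list(statistic = unname(k$statistic), p = k$p.value,
         method = "kruskal-wallis")
  } else {
    a <- stats::oneway.test(values ~ labels, var.equal = TRUE)
    list(statistic = unname(a$statistic), p = a$p.value, method = "anova")
  }
}

# Two-sided rank-sum test. Exact path enumerates all C(n, n1) assignments of
# the pooled average ranks to group 1 and counts splits at least as extreme
# (in |W - E W|) as observed.
wilcoxon_ranksum <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y), ties.method = "average")
  w_obs <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    splits <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[splits], nrow = n1))
    p <- mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
    list(statistic = w_obs, p = p, method = "wilcoxon (exact)")
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (w_obs - ew) / sqrt(v)
    list(statistic = w_obs, p = 2 * stats::pnorm(-abs(z)),
         method = "wilcoxon (normal approximation)")
  }
}

#' Contingency-table test
#'
#' Chi-square (without continuity correction) or Fisher's exact test for a
#' 2 x 2 table. Fisher on larger tables falls back to chi-square with a
#' warning; rows or columns with zero margin are dropped with a warning
#' before testing.
#'
#' @param counts matrix (or table) of non-negative integer counts.
#' @param method `"chisq"` or `"fisher"`.
#' @return list with `statistic` (NA for fisher), `p`, `method`.
#' @export
contingency_test <- function(counts, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("table degenerate after dropping zero margins", call. = FALSE)
  if (method == "fisher" && !all(dim(counts) == c(2L, 2L))) {
    warning("fisher restricted to 2x2 tables; using chi-square",
            call. = FALSE)
    method <- "chisq"
  }
  if (method == "fisher") {
    f <- stats::fisher.test(counts)
    list(statistic = NA_real_, p = f$p.value, method = "fisher")
  } else {
    cs <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(statistic = unname(cs$statistic), p = cs$p.value, method = "chisq")
  }
}

#' Baseline-characteristics summary table by subtype
#'
#' Builds a Table-1-style cohort summary: for categorical variables, per
#' level the count and the percentage of the column total (1 decimal, half
#' rounded up); for numeric variables, mean (SD) and median [min, max].
#' Per-variable p-values compare subtypes: categorical variables by
#' chi-square, or Fisher's exact test when the complete-case table is 2 x 2;
#' numeric variables by one-way ANOVA. `NA` values form an explicit "NA"
#' category that is tallied but excluded from tests. With a single subtype
#' all tests are skipped.
#'
#' @param clinical data.frame of covariates, one row per sample.
#' @param labels subtype labels, same length/order as `clinical` rows.
#' @return data.frame with columns `variable`, `level`, `Overall`, one
#'   column per subtype, `p`, `method`.
#' @export
cohort_summary <- function(clinical, labels) {
  labels <- factor(labels)
  if (length(labels) != nrow(clinical))
    stop("every sample must be labeled", call. = FALSE)
  groups <- levels(labels)
  n_tot <- length(labels)
  n_grp <- table(labels)

  header <- data.frame(variable = "n", level = "",
                       Overall = as.character(n_tot),
                       matrix(sprintf("%d (%s)", as.integer(n_grp),
                                      vapply(as.integer(n_grp), fmt_pct, "",
                                             denom = n_tot)),
                              nrow = 1, dimnames = list(NULL, groups)),
                       p = NA_real_, method = "", check.names = FALSE)
  rows <- list(header)

  for (v in names(clinical)) {
    x <- clinical[[v]]
    if (is.numeric(x)) {
      fmt1 <- function(idx) {
        xi <- x[idx]; xi <- xi[!is.na(xi)]
        if (!length(xi)) return(c("NA", "NA"))
        c(sprintf("%.1f (%.2f)", round_half_up(mean(xi), 1), stats::sd(xi)),
          sprintf("%.1f [%.1f, %.1f]", stats::median(xi), min(xi), max(xi)))
      }
      cells <- cbind(fmt1(seq_len(n_tot)),
                     vapply(groups, function(g) fmt1(labels == g),
                            character(2)))
      p <- NA_real_; meth <- "skipped"
      if (length(groups) > 1 && sum(!is.na(x)) > length(groups)) {
        cc <- !is.na(x)
        if (nlevels(droplevels(labels[cc])) > 1 &&
            length(unique(x[cc])) > 1) {
          gc <- tryCatch(group_compare(x[cc], labels[cc], test = "anova"),
                         error = function(e) NULL)
          if (!is.null(gc)) { p <- gc$p; meth <- gc$method }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = c("Mean (SD)", "Median [Min, Max]"),
        Overall = cells[, 1],
        matrix(cells[, -1, drop = FALSE], nrow = 2,
               dimnames = list(NULL, groups)),
        p = c(p, NA), method = c(meth, ""), check.names = FALSE)
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "NA"
      lev <- unique(x)
      lev <- c(setdiff(lev, "NA"), intersect("NA", lev))
      cell <- function(idx, l)
        sprintf("%d (%s)", sum(x[idx] == l), fmt_pct(sum(x[idx] == l),
                                                     length(idx)))
      gm <- matrix(vapply(groups, function(g)
        vapply(lev, function(l) cell(which(labels == g), l), ""),
        character(length(lev))), nrow = length(lev),
        dimnames = list(NULL, groups))
      block <- data.frame(
        variable = v, level = lev,
        Overall = vapply(lev, function(l) cell(seq_len(n_tot), l), ""),
        gm, p = NA_real_, method = "", check.names = FALSE)
      if (length(groups) > 1) {
        keep <- x != "NA"
        tab <- table(x[keep], labels[keep])
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (nrow(tab) >= 2 && ncol(tab) >= 2) {
          meth <- if (all(dim(tab) == c(2L, 2L))) "fisher" else "chisq"
          ct <- suppressWarnings(contingency_test(tab, method = meth))
          block$p[1] <- ct$p
          block$method[1] <- ct$method
        } else block$method[1] <- "skipped"
      } else block$method[1] <- "skipped"
      rows[[length(rows) + 1]] <- block
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
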