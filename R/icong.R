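# The Icong congruence index: observed MAST size divided by the expected
# MAST size of two random trees on the same number of leaves, with a p-value
# for the null hypothesis that the trees are no more congruent than chance.
#
# Two calibration back-ends are provided.
#
# * "regression": E(MAST | n) = a * n^b with a null tail model
#   p(k, n) = min(1, exp(-g * (k - E(n) - h))). The default constants were
#   calibrated once against the discrete grid of published Icong values for
#   n = 27 (unit E = 7.5835, consecutive integer MAST sizes k = 8..16) and a
#   power-law fit to Monte-Carlo expected MAST sizes of uniform (PDA) random
#   rooted tree pairs across n; the tail slope/shift are a least-squares fit
#   of log p against k on the same published grid.
#
# * "montecarlo": an empirical null built by drawing R independent random
#   tree pairs (Yule or PDA) and recording their exact MAST sizes;
#   E(MAST | n) is the null mean and p uses the add-one estimator, so p is
#   never zero and never larger than 1.

.icong_regression_defaults <- list(
  a = 1.443877,
  b = 0.503254,
  p_slope = 2.06071822659269,
  p_shift = 16.06349214591279 / 2.06071822659269 - 1.443877 * 27^0.503254
)

#' Calibrate the expected MAST size for n-leaf trees
#'
#' @param n leaf count, at least 4.
#' @param mode `"montecarlo"` (self-contained default) or `"regression"`
#'   (constants calibrated against the published Icong grid).
#' @param null_model random-tree null for Monte-Carlo mode: `"yule"` or
#'   `"pda"`.
#' @param R number of Monte-Carlo replicates (>= 100).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param rooted calibrate for rooted MAST (default) or unrooted?
#' @param a,b,p_slope,p_shift regression constants; defaults as described in
#'   the package vignette.
#' @return an object of class `icong_calibration`.
#' @export
icong_calibration <- function(n, mode = c("montecarlo", "regression"),
                              null_model = c("yule", "pda"), R = 2000L,
                              seed = 1L, rooted = TRUE,
                              a = .icong_regression_defaults$a,
                              b = .icong_regression_defaults$b,
                              p_slope = .icong_regression_defaults$p_slope,
                              p_shift = .icong_regression_defaults$p_shift) {
  mode <- match.arg(mode)
  null_model <- match.arg(null_model)
  check_that(is.numeric(n) && length(n) == 1L && n == round(n) && n >= 4,
             "'n' must be an integer >= 4")
  n <- as.integer(n)
  if (mode == "regression") {
    E <- a * n^b
    check_that(E > 1 && E < n, "regression calibration gives E(MAST) outside (1, n)")
    cal <- list(mode = "regression", n = n, rooted = rooted,
                a = a, b = b, p_slope = p_slope, p_shift = p_shift,
                expected_mast = E)
  } else {
    check_that(is.numeric(R) && R >= 100, "'R' must be >= 100")
    R <- as.integer(R)
    mast_fun <- if (rooted) mast_rooted else mast_unrooted
    sizes <- with_seed(seed, {
      vapply(seq_len(R), function(i) {
        s1 <- sample.int(.Machine$integer.max / 2, 2L)
        t1 <- random_tree(n, null_model, seed = s1[1L])
        t2 <- random_tree(n, null_model, seed = s1[2L])
        mast_fun(t1, t2)$size
      }, 0L)
    })
    E <- mean(sizes)
    check_that(E > 1 && E < n, "Monte-Carlo calibration gives E(MAST) outside (1, n)")
    cal <- list(mode = "montecarlo", n = n, rooted = rooted,
                null_model = null_model, R = R, seed = as.integer(seed),
                null_sizes = sizes, expected_mast = E)
  }
  class(cal) <- "icong_calibration"
  cal
}

#' @export
print.icong_calibration <- function(x, ...) {
  cat("Icong calibration (", x$mode, "), n = ", x$n, ", ",
      if (x$rooted) "rooted" else "unrooted", " MAST\n", sep = "")
  cat("  E(MAST | n) = ", format(x$expected_mast, digits = 6), "\n", sep = "")
  if (x$mode == "montecarlo")
    cat("  null: ", x$null_model, ", R = ", x$R, ", seed = ", x$seed, "\n", sep = "")
  else
    cat("  E = ", format(x$a, digits = 6), " * n^", format(x$b, digits = 6),
        "; ln p = -", format(x$p_slope, digits = 6), " * (k - E - ",
        format(x$p_shift, digits = 6), ")\n", sep = "")
  invisible(x)
}

# p-value of observing MAST >= k under the calibration's null
icong_p_value <- function(cal, k) {
  if (cal$mode == "regression") {
    p <- exp(-cal$p_slope * (k - cal$expected_mast - cal$p_shift))
    return(min(1, p))
  }
  (1 + sum(cal$null_sizes >= k)) / (cal$R + 1)
}

#' Icong congruence test for a pair of trees
#'
#' Computes the exact MAST size of the pair, the congruence index
#' Icong = MAST / E(MAST | n), and a p-value for the hypothesis that the two
#' trees are no more topologically congruent than two independent random
#' trees on the same leaves. p < 0.05 indicates significant congruence.
#'
#' @param t1,t2 trees (`phylo`) on the same leaf set.
#' @param calibration an [icong_calibration] built for the same leaf count.
#' @param labels length-2 character vector naming the two trees in the
#'   result.
#' @return an object of class `congruence_result` with fields `labels`, `n`,
#'   `mast`, `icong`, `p`, `significant`, `calibration`.
#' @export
icong_test <- function(t1, t2, calibration,
                       labels = c(deparse(substitute(t1))[1L],
                                  deparse(substitute(t2))[1L])) {
  check_that(inherits(calibration, "icong_calibration"),
             "'calibration' must be an icong_calibration")
  validate_tree(t1); validate_tree(t2)
  check_same_leaves(t1, t2)
  n <- length(t1$tip.label)
  if (n != calibration$n)
    stop("calibration was built for n = ", calibration$n,
         " leaves but the trees have ", n, call. = FALSE)
  m <- if (calibration$rooted) mast_rooted(t1, t2) else mast_unrooted(t1, t2)
  icong <- m$size / calibration$expected_mast
  p <- icong_p_value(calibration, m$size)
  structure(list(labels = labels, n = n, mast = m$size, witness = m$witness,
                 icong = icong, p = p, significant = p < 0.05,
                 calibration = calibration),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat("Icong congruence test: ", x$labels[1L], " vs ", x$labels[2L], "\n", sep = "")
  cat("  n = ", x$n, ", MAST = ", x$mast,
      ", Icong = ", sprintf("%.2f", x$icong),
      "; p = ", format(signif(x$p, 3)), "\n", sep = "")
  cat(if (x$significant)
    "  more congruent than expected by chance (p < 0.05)\n"
    else "  NOT more congruent than expected by chance (p > 0.05)\n")
  invisible(x)
}

#' All-vs-all congruence table
#'
#' Runs [icong_test] on every unordered pair of a named tree collection
#' sharing one leaf set.
#'
#' @param trees named list of `phylo` objects on one common leaf set.
#' @param calibration an [icong_calibration] for that leaf count.
#' @return a data.frame of class `congruence_table` with one row per pair:
#'   `tree1`, `tree2`, `n`, `mast`, `icong`, `p`, `significant`.
#' @export
congruence_table <- function(trees, calibration) {
  check_that(is.list(trees) && length(trees) >= 2L,
             "'trees' must be a list of at least two trees")
  nm <- names(trees)
  check_that(!is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm),
             "'trees' must have unique non-empty names")
  base <- trees[[1L]]$tip.label
  for (i in seq_along(trees)) {
    validate_tree(trees[[i]], paste0("tree '", nm[i], "'"))
    if (!setequal(trees[[i]]$tip.label, base))
      stop("mixed leaf sets: tree '", nm[i],
           "' does not share the leaf set of '", nm[1L], "'", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(trees)[-1L]) for (j in seq_len(i - 1L)) {
    r <- icong_test(trees[[i]], trees[[j]], calibration, labels = c(nm[i], nm[j]))
    rows[[length(rows) + 1L]] <-
      data.frame(tree1 = nm[i], tree2 = nm[j], n = r$n, mast = r$mast,
                 icong = r$icong, p = r$p, significant = r$significant,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "calibration") <- calibration
  class(out) <- c("congruence_table", "data.frame")
  out
}

# "Icong; p" display cell, mirroring the published rounding (Icong to two
# decimals, p to three significant figures); non-significant cells flagged
format_cell_ <- function(icong, p, flag = "*") {
  paste0(sprintf("%.2f", icong), "; ", format(signif(p, 3)),
         if (p > 0.05) flag else "")
}

#' @export
print.congruence_table <- function(x, ...) {
  cat("Pairwise Icong congruence table (", nrow(x), " pairs, n = ",
      x$n[1L], " leaves)\n", sep = "")
  print(format_congruence_matrix(x), quote = FALSE)
  cat("cells: 'Icong; p'; * marks pairs not more congruent than chance (p > 0.05)\n")
  invisible(x)
}

# lower-triangular character matrix of display cells
format_congruence_matrix <- function(tab) {
  nm <- unique(c(tab$tree2, tab$tree1))
  out <- matrix("", length(nm) - 1L, length(nm) - 1L,
                dimnames = list(nm[-1L], nm[-length(nm)]))
  for (r in seq_len(nrow(tab))) {
    out[tab$tree1[r], tab$tree2[r]] <- format_cell_(tab$icong[r], tab$p[r])
  }
  out
}

#' Write a congruence table as TSV and Markdown
#'
#' The TSV holds one row per pair with full-precision values; the Markdown
#' file renders the lower-triangular "Icong; p" table with non-significant
#' cells marked by `*`.
#'
#' @param tab a [congruence_table].
#' @param tsv_path,md_path output paths (either may be `NULL` to skip).
#' @return invisible list of the paths written.
#' @export
write_congruence_report <- function(tab, tsv_path = NULL, md_path = NULL) {
  check_that(inherits(tab, "congruence_table"), "'tab' must be a congruence_table")
  if (!is.null(tsv_path)) {
    df <- as.data.frame(tab)
    df$icong <- sprintf("%.6f", df$icong)
    df$p <- sprintf("%.6g", df$p)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(md_path)) {
    mat <- format_congruence_matrix(tab)
    hdr <- paste0("| ", paste(c("", colnames(mat)), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(mat) + 1L), collapse = "|"), "|")
    body <- vapply(rownames(mat), function(rn)
      paste0("| ", paste(c(rn, mat[rn, ]), collapse = " | "), " |"), "")
    writeLines(c(hdr, sep, body, "",
                 paste("Cells show `Icong; p`;",
                       "`*` marks pairs not more congruent than expected",
                       "by chance (p > 0.05).")),
               md_path)
  }
  invisible(list(tsv = tsv_path, md = md_path))
}

#' Fit the discrete Icong grid of a set of index values
#'
#' Published Icong values for a fixed leaf count lie on the grid k / E for
#' integer MAST sizes k. Given a set of (rounded) index values, this
#' brute-force search recovers the common unit E and the integer multiples k
#' minimizing the squared rounding error.
#'
#' @param values numeric Icong values (each > 0), distinct after sorting.
#' @param E_range length-2 numeric search interval for E.
#' @param step search grid step.
#' @param consecutive require the multiples of the sorted distinct values to
#'   be consecutive integers? This pins down the unit: without it, any
#'   integer multiple of a fitting E fits as well (k and E scale together),
#'   and a large enough E can overfit values that were rounded for display.
#' @return list with `E` (fitted unit), `k` (integer multiples, one per
#'   value, in input order), and `rmse`.
#' @export
fit_icong_grid <- function(values, E_range = c(2, 20), step = 5e-4,
                           consecutive = TRUE) {
  check_that(is.numeric(values) && length(values) >= 2L && all(values > 0),
             "'values' must be positive numerics")
  vs <- sort(unique(values))
  Es <- seq(E_range[1L], E_range[2L], by = step)
  sse <- vapply(Es, function(E) sum((values - round(values * E) / E)^2), 0)
  if (consecutive) {
    ok <- vapply(Es, function(E) all(diff(round(vs * E)) == 1), TRUE)
    if (!any(ok))
      stop("no unit in E_range puts the values on consecutive integer ",
           "multiples; try consecutive = FALSE", call. = FALSE)
    sse[!ok] <- Inf
  }
  best <- min(sse)
  E <- min(Es[sse <= best * (1 + 1e-9) + 1e-15])
  list(E = E, k = as.integer(round(values * E)),
       rmse = sqrt(best / length(values)))
}
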