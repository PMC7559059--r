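# UPGMA phenograms from species distance matrices.

#' Average-linkage (UPGMA) phenogram
#'
#' Agglomerative clustering: at each step the pair of clusters with the
#' smallest unweighted average inter-cluster distance is merged, at height
#' equal to half that distance. The result is a rooted, binary, ultrametric
#' tree whose branch lengths are differences of merge heights.
#'
#' Ties are broken deterministically and independently of input order: each
#' cluster is represented by its lexicographically smallest member label, and
#' among equal-distance candidate merges the pair whose sorted representative
#' pair is smallest is chosen.
#'
#' @param d a `dist` object or a symmetric numeric matrix with zero diagonal,
#'   labelled by species, at least 2 species.
#' @return a `phylo` object of class `c("phenogram", "phylo")` with branch
#'   lengths; `attr(tree, "merge_heights")` records the successive merge
#'   heights.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  check_that(n >= 2L, "need at least 2 species")
  labs <- rownames(m)
  if (is.null(labs)) labs <- colnames(m)
  check_that(!is.null(labs) && all(nzchar(labs)) && !anyDuplicated(labs),
             "distance matrix must carry unique species labels")
  rownames(m) <- colnames(m) <- labs
  if (anyNA(m) || !isSymmetric(unname(m)))
    stop("distance matrix must be symmetric without NAs", call. = FALSE)
  if (any(m < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal", call. = FALSE)

  # active clusters: newick fragment, representative label, size, height
  nwk <- labs
  rep_ <- labs
  size <- rep(1, n)
  height <- rep(0, n)
  active <- seq_len(n)
  merge_heights <- numeric(0)

  while (length(active) > 1L) {
    k <- length(active)
    best <- NULL
    for (ii in 1:(k - 1L)) for (jj in (ii + 1L):k) {
      i <- active[ii]; j <- active[jj]
      dij <- m[i, j]
      r1 <- min(rep_[i], rep_[j]); r2 <- max(rep_[i], rep_[j])
      if (is.null(best) || dij < best$d ||
          (dij == best$d && (r1 < best$r1 || (r1 == best$r1 && r2 < best$r2))))
        best <- list(i = i, j = j, d = dij, r1 = r1, r2 = r2)
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    merge_heights <- c(merge_heights, h)
    # unweighted average update into slot i
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      newd <- (size[i] * m[i, others] + size[j] * m[j, others]) / (size[i] + size[j])
      m[i, others] <- newd; m[others, i] <- newd
    }
    nwk[i] <- paste0("(", nwk[i], ":", format(h - height[i], digits = 15),
                     ",", nwk[j], ":", format(h - height[j], digits = 15), ")")
    rep_[i] <- best$r1
    size[i] <- size[i] + size[j]
    height[i] <- h
    active <- setdiff(active, j)
  }
  phy <- parse_newick(paste0(nwk[active], ";"))
  attr(phy, "merge_heights") <- merge_heights
  class(phy) <- c("phenogram", class(phy))
  phy
}

#' @export
print.phenogram <- function(x, ...) {
  cat("UPGMA phenogram: ", length(x$tip.label), " species, root height ",
      format(max(attr(x, "merge_heights"))), "\n", sep = "")
  cat(write_newick(x), "\n")
  invisible(x)
}
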