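# Protein-content matrices: families x species integer count tables with a
# category label, plus their transformation into species distance matrices.

#' Construct a protein-content matrix
#'
#' A PC matrix records, for each protein family (rows, e.g. Pfam accessions)
#' and each species (columns, short species codes), the number of member
#' proteins of that family in that species' proteome.
#'
#' @param counts integer matrix (families x species) with unique, non-empty
#'   rownames (family ids) and colnames (species codes); all entries
#'   nonnegative integers.
#' @param category category label, e.g. `"whole_genome"`, `"CAZy"`,
#'   `"cell_wall"`.
#' @return an object of class `pc_matrix` (an integer matrix with a
#'   `category` attribute).
#' @export
pc_matrix <- function(counts, category = "whole_genome") {
  check_that(is.matrix(counts), "'counts' must be a matrix")
  check_that(is.character(category) && length(category) == 1L && nzchar(category),
             "'category' must be a single non-empty string")
  rn <- rownames(counts); cn <- colnames(counts)
  check_that(!is.null(rn) && all(nzchar(rn)), "family ids (rownames) required")
  check_that(!is.null(cn) && all(nzchar(cn)), "species codes (colnames) required")
  dup <- unique(rn[duplicated(rn)])
  if (length(dup)) stop("duplicate family ids: ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(cn[duplicated(cn)])
  if (length(dup)) stop("duplicate species codes: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyNA(counts)) stop("counts contain NA", call. = FALSE)
  if (!is.numeric(counts) || any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(counts, category = category, class = c("pc_matrix", "matrix", "array"))
}

#' @export
print.pc_matrix <- function(x, ...) {
  cat("Protein-content matrix [", attr(x, "category"), "]: ",
      nrow(x), " families x ", ncol(x), " species\n", sep = "")
  cat("  total count ", sum(x), "; families present in all species: ",
      sum(rowSums(x > 0L) == ncol(x)), "\n", sep = "")
  invisible(x)
}

#' @export
`[.pc_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, category = attr(x, "category"),
                     class = c("pc_matrix", "matrix", "array"))
  out
}

#' Read a protein-content matrix from a TSV file
#'
#' Expected layout: a header row of species codes, first column of family
#' ids, integer cells.
#'
#' @param path path to the TSV file.
#' @param category category label attached to the matrix.
#' @return a [pc_matrix].
#' @export
read_pc_matrix <- function(path, category = "whole_genome") {
  check_that(file.exists(path), paste0("file not found: ", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2L) stop("no data rows in ", path, call. = FALSE)
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": rows have ", paste(unique(nf), collapse = "/"),
         " fields", call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          quote = "", stringsAsFactors = FALSE)
  check_that(ncol(df) >= 2L, "need a family-id column plus at least one species column")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-integer cell at family '", ids[bad[1L, 1L]], "', species '",
         colnames(vals)[bad[1L, 2L]], "': '", vals[bad[1L, 1L], bad[1L, 2L]], "'",
         call. = FALSE)
  dimnames(num) <- list(ids, colnames(vals))
  pc_matrix(num, category)
}

#' Write a protein-content matrix as TSV
#'
#' @param m a [pc_matrix].
#' @param path output path.
#' @param id_column name of the first (family id) column in the header.
#' @return `path`, invisibly.
#' @export
write_pc_matrix <- function(m, path, id_column = "family") {
  check_that(inherits(m, "pc_matrix"), "'m' must be a pc_matrix")
  df <- data.frame(rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove protein families present in too few species
#'
#' Curation step: families with a nonzero count in fewer than `min_presence`
#' species are removed (the default removes families present in only one or
#' two species, which are typically gene-annotation artefacts). The species
#' set is unchanged. Idempotent.
#'
#' @param m a [pc_matrix].
#' @param min_presence minimum number of species with a nonzero count.
#' @param quiet suppress the removal message?
#' @return the filtered [pc_matrix].
#' @export
filter_rare_families <- function(m, min_presence = 3L, quiet = FALSE) {
  check_that(inherits(m, "pc_matrix"), "'m' must be a pc_matrix")
  check_that(is.numeric(min_presence) && length(min_presence) == 1L &&
               min_presence >= 1, "'min_presence' must be an integer >= 1")
  presence <- rowSums(unclass(m) > 0L)
  keep <- presence >= min_presence
  if (!quiet)
    message("filter_rare_families: removed ", sum(!keep), " of ", nrow(m),
            " families present in < ", min_presence, " species")
  if (!any(keep))
    warning("all families removed by the rare-family filter", call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Extract family-category submatrices
#'
#' With a character vector, returns the submatrix of those families. With a
#' named list mapping category names to family-id vectors, returns one
#' submatrix per category.
#'
#' @param m a [pc_matrix].
#' @param families character vector of family ids, or a named list of such
#'   vectors (category -> ids).
#' @param category category label for the single-subset form (defaults to the
#'   source label).
#' @return a [pc_matrix], or a named list of them.
#' @export
subset_families <- function(m, families, category = NULL) {
  check_that(inherits(m, "pc_matrix"), "'m' must be a pc_matrix")
  if (is.list(families)) {
    check_that(!is.null(names(families)) && all(nzchar(names(families))),
               "the category mapping must be a named list")
    return(mapply(function(ids, cat) subset_families(m, ids, category = cat),
                  families, names(families), SIMPLIFY = FALSE))
  }
  families <- as.character(families)
  check_that(length(families) >= 1L, "empty family set requested")
  unknown <- setdiff(families, rownames(m))
  if (length(unknown))
    stop("unknown family ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- m[families, , drop = FALSE]
  attr(out, "category") <- if (is.null(category)) attr(m, "category") else category
  out
}

#' Pearson-correlation distances between species
#'
#' For each species pair the Pearson correlation r of their family-count
#' vectors is computed and transformed to a dissimilarity, by default
#' d = 1 - r (range \[0, 2\]); `transform = "half"` gives (1 - r)/2.
#' Optionally counts are log1p-transformed first.
#'
#' @param m a [pc_matrix] with at least 2 families.
#' @param transform `"one_minus_r"` (default) or `"half"`.
#' @param log1p apply `log1p` to the counts before correlating?
#' @return a `dist` object over the species codes.
#' @export
correlation_distance <- function(m, transform = c("one_minus_r", "half"),
                                 log1p = FALSE) {
  check_that(inherits(m, "pc_matrix"), "'m' must be a pc_matrix")
  transform <- match.arg(transform)
  check_that(nrow(m) >= 2L, "need at least 2 families to correlate")
  x <- unclass(m)
  storage.mode(x) <- "double"
  if (log1p) x <- log1p(x)
  vars <- apply(x, 2L, stats::var)
  if (any(vars == 0))
    stop("zero-variance species column(s): ",
         paste(colnames(m)[vars == 0], collapse = ", "),
         " (Pearson correlation undefined)", call. = FALSE)
  r <- stats::cor(x)
  d <- 1 - r
  if (transform == "half") d <- d / 2
  d[d < 0] <- 0  # guard against -0 / rounding noise at r = 1
  stats::as.dist(d)
}
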