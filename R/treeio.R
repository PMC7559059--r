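#' @importFrom ape read.tree write.tree keep.tip prop.part
NULL

# ---- internal helpers -------------------------------------------------------

# Minimal single-leaf phylo (ape functions mostly refuse Ntip = 1, but the
# data model needs it for degenerate restrictions).
single_leaf_tree <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 tip.label = label, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

is_single_leaf <- function(phy) inherits(phy, "phylo") && length(phy$tip.label) == 1L

# children list / leaf map representation used by the MAST dynamic program
# and the tree generators. Nodes keep ape numbering: tips 1..n, root n+1.
as_childlist <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  children <- vector("list", nn)
  for (i in seq_len(nn)) children[[i]] <- integer(0)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  list(children = children, root = n + 1L, ntip = n, nnode = nn,
       tip.label = phy$tip.label)
}

# recursive newick emitter for a children-list tree; lengths optional vector
# of per-node branch lengths (length to parent), NULL to omit
childlist_newick <- function(children, root, labels, lengths = NULL) {
  emit <- function(v) {
    s <- if (length(children[[v]]) == 0L) labels[v]
    else paste0("(", paste(vapply(children[[v]], emit, ""), collapse = ","), ")")
    if (!is.null(lengths) && !is.na(lengths[v])) s <- paste0(s, ":", lengths[v])
    s
  }
  paste0(emit(root), ";")
}

validate_tree <- function(phy, what = "tree") {
  check_that(inherits(phy, "phylo"), paste(what, "is not a 'phylo' object"))
  labs <- phy$tip.label
  check_that(!anyNA(labs) && all(nzchar(labs)), paste(what, "has empty leaf labels"))
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop(what, " has duplicate leaf labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  invisible(phy)
}

check_same_leaves <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf sets (only in first: ",
         paste(setdiff(a$tip.label, b$tip.label), collapse = ", "),
         "; only in second: ",
         paste(setdiff(b$tip.label, a$tip.label), collapse = ", "), ")",
         call. = FALSE)
  invisible(TRUE)
}

# ---- Newick I/O -------------------------------------------------------------

#' Parse a single Newick string
#'
#' Leaf names may be bare alphanumeric/underscore tokens or quoted strings;
#' quoting is accepted on read but never emitted. Internal node labels are
#' ignored. Branch lengths, when present, are retained.
#'
#' @param text a Newick string terminated by `";"`.
#' @return an object of class `phylo`.
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  check_that(is.character(text) && length(text) == 1L, "'text' must be a single string")
  txt <- trimws(text)
  check_that(nzchar(txt), "empty Newick string")
  if (!grepl(";", txt, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at position ", nchar(txt),
         call. = FALSE)
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at position ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at position ", nchar(txt),
         call. = FALSE)
  # degenerate single-leaf tree, e.g. "A;"
  if (grepl("^[^(),;:]+(:[0-9.eE+-]+)?;$", txt)) {
    lab <- sub("^([^(),;:]+).*$", "\\1", txt)
    return(single_leaf_tree(gsub("^['\"]|['\"]$", "", lab)))
  }
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("Newick parse error: malformed string: ", substr(txt, 1, 60), call. = FALSE)
  phy$node.label <- NULL
  validate_tree(phy, "parsed tree")
}

#' Read trees from a Newick file
#'
#' One tree per line or a single tree spanning the file; returns a list of
#' `phylo` objects.
#'
#' @param path path to a Newick file (UTF-8).
#' @return list of `phylo` objects.
#' @export
read_newick <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  check_that(length(parts) >= 1L, paste0("no trees found in ", path))
  lapply(paste0(parts, ";"), parse_newick)
}

#' Write a tree as a Newick string
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written there.
#' @param include_lengths keep branch lengths (if any) in the output?
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, include_lengths = TRUE) {
  validate_tree(tree)
  if (is_single_leaf(tree)) {
    s <- paste0(tree$tip.label, ";")
  } else {
    phy <- tree
    if (!include_lengths) phy$edge.length <- NULL
    class(phy) <- "phylo"  # drop subclasses for ape
    s <- ape::write.tree(phy)
  }
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# ---- tree surgery -----------------------------------------------------------

#' Restrict a tree to a subset of its leaves
#'
#' Returns the topology induced on `keep`, with unary internal nodes
#' suppressed. Restriction to the full leaf set returns the tree unchanged;
#' restriction to one leaf returns a single-leaf tree.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of leaf labels, a subset of the tree's leaves.
#' @return a `phylo` object with `length(keep)` leaves.
#' @export
restrict_to_leaves <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  check_that(length(keep) >= 1L, "'keep' must contain at least one label")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("labels not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) return(single_leaf_tree(keep))
  ape::keep.tip(tree, keep)
}

#' Reroot a tree on one of its edges
#'
#' Places the root on the chosen edge of the unrooted topology underlying
#' `tree`. The result is a rooted tree with the same unrooted topology.
#' Branch lengths are dropped: rerooting is a topology operation here.
#'
#' @param tree a `phylo` object with at least 2 leaves.
#' @param edge integer row index into `tree$edge`.
#' @return a rooted `phylo` object.
#' @export
reroot_on_edge <- function(tree, edge) {
  validate_tree(tree)
  check_that(!is_single_leaf(tree), "cannot reroot a single-leaf tree")
  ne <- nrow(tree$edge)
  if (!(is.numeric(edge) && length(edge) == 1L && !is.na(edge) &&
        edge == round(edge) && edge >= 1 && edge <= ne))
    stop("invalid edge id: must be an integer in 1..", ne, call. = FALSE)
  n <- length(tree$tip.label)
  if (n == 2L) return(tree)  # single cherry: only one unrooted shape
  root <- n + 1L
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(ne)) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  u <- tree$edge[edge, 1L]; v <- tree$edge[edge, 2L]
  # suppress a degree-2 root: its two incident edges are one unrooted edge
  if (length(adj[[root]]) == 2L) {
    kids <- adj[[root]]
    adj[[kids[1L]]] <- c(setdiff(adj[[kids[1L]]], root), kids[2L])
    adj[[kids[2L]]] <- c(setdiff(adj[[kids[2L]]], root), kids[1L])
    adj[[root]] <- integer(0)
    if (u == root) u <- setdiff(kids, v)
  }
  # orient away from the new root placed on edge (u, v)
  children <- vector("list", nn + 1L)
  for (i in seq_len(nn + 1L)) children[[i]] <- integer(0)
  newroot <- nn + 1L
  children[[newroot]] <- c(u, v)
  blocked <- c(v, u)  # when descending from u do not cross to v, and vice versa
  for (k in 1:2) {
    start <- c(u, v)[k]
    stack <- start; prev <- c(blocked[k])
    names(prev) <- as.character(start)
    while (length(stack)) {
      w <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (x in adj[[w]]) {
        if (x == prev[[as.character(w)]]) next
        children[[w]] <- c(children[[w]], x)
        prev[[as.character(x)]] <- w
        stack <- c(stack, x)
      }
    }
  }
  labels <- character(nn + 1L)
  labels[seq_len(n)] <- tree$tip.label
  parse_newick(childlist_newick(children, newroot, labels))
}

# ---- topology comparison ----------------------------------------------------

#' Clusters (clades) of a rooted tree
#'
#' Returns one key per internal node: the sorted leaf labels of its clade
#' joined by `"|"`. The root cluster (all leaves) is included; singletons are
#' not.
#'
#' @param tree a `phylo` object.
#' @return character vector of cluster keys.
#' @export
tree_clusters <- function(tree) {
  validate_tree(tree)
  if (is_single_leaf(tree)) return(character(0))
  pp <- ape::prop.part(tree)
  unique(vapply(pp, function(idx)
    paste(sort(tree$tip.label[idx]), collapse = "|"), ""))
}

# nontrivial splits of the unrooted topology, canonicalised to the side
# containing the alphabetically smallest leaf
tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  anchor <- labs[1L]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (idx in pp) {
    side <- sort(tree$tip.label[idx])
    if (length(side) < 2L || length(side) > n - 2L) next
    if (!(anchor %in% side)) side <- setdiff(labs, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Topological identity of two trees on the same leaf set
#'
#' Rooted comparison tests equality of cluster sets; unrooted comparison tests
#' equality of nontrivial split sets.
#'
#' @param a,b `phylo` objects with identical leaf sets.
#' @param rooted compare as rooted trees (clusters) or unrooted (splits)?
#' @return `TRUE` or `FALSE`.
#' @export
same_topology <- function(a, b, rooted = TRUE) {
  validate_tree(a); validate_tree(b)
  check_same_leaves(a, b)
  if (rooted) setequal(tree_clusters(a), tree_clusters(b))
  else setequal(tree_splits(a), tree_splits(b))
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the cluster sets (rooted) or the
#' nontrivial split sets (unrooted) of two trees on the same leaves. Zero if
#' and only if the topologies are identical.
#'
#' @inheritParams same_topology
#' @return nonnegative integer.
#' @export
rf_distance <- function(a, b, rooted = TRUE) {
  validate_tree(a); validate_tree(b)
  check_same_leaves(a, b)
  ca <- if (rooted) tree_clusters(a) else tree_splits(a)
  cb <- if (rooted) tree_clusters(b) else tree_splits(b)
  length(setdiff(ca, cb)) + length(setdiff(cb, ca))
}

# ---- random trees -----------------------------------------------------------

#' Random rooted binary tree topologies
#'
#' `model = "yule"` grows the tree by splitting a uniformly chosen pending
#' leaf (the equal-rates-Markov shape distribution); `model = "pda"` performs
#' stepwise addition on a uniformly chosen edge, root edge included, which
#' yields the uniform (PDA) distribution over labelled rooted topologies.
#' Leaf labels are assigned by a random permutation so that labelled
#' topologies are exchangeable. Deterministic given `(n, model, seed)`.
#'
#' @param n number of leaves, at least 2.
#' @param model `"yule"` or `"pda"`.
#' @param seed integer seed.
#' @param labels optional character vector of `n` distinct labels
#'   (default `"t01"`, `"t02"`, ...).
#' @return a rooted binary `phylo` object without branch lengths.
#' @export
random_tree <- function(n, model = c("yule", "pda"), seed, labels = NULL) {
  model <- match.arg(model)
  check_that(is.numeric(n) && length(n) == 1L && n == round(n) && n >= 2,
             "'n' must be an integer >= 2")
  n <- as.integer(n)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n))
  check_that(length(labels) == n && !anyDuplicated(labels),
             "'labels' must be n distinct strings")
  with_seed(seed, {
    tr <- if (model == "yule") yule_topology_(n) else pda_topology_(n)
    perm <- sample.int(n)
    labs <- character(tr$nnode)
    labs[!is.na(tr$leafof)] <- labels[perm[tr$leafof[!is.na(tr$leafof)]]]
    parse_newick(childlist_newick(tr$children, tr$root, labs))
  })
}

# internal generators on the children-list representation; leaves carry an
# integer id in leafof, internal nodes NA
yule_topology_ <- function(n) {
  children <- vector("list", 2L * n - 1L)
  for (i in seq_along(children)) children[[i]] <- integer(0)
  children[[1L]] <- c(2L, 3L)
  leafof <- c(NA, 1L, 2L, rep(NA, 2L * n - 4L))
  leaves <- c(2L, 3L)
  nleaf <- 2L; nn <- 3L
  while (nleaf < n) {
    j <- sample.int(length(leaves), 1L)
    v <- leaves[j]
    a <- nn + 1L; b <- nn + 2L
    children[[v]] <- c(a, b)
    leafof[a] <- leafof[v]; leafof[b] <- nleaf + 1L; leafof[v] <- NA
    leaves[j] <- a; leaves <- c(leaves, b)
    nleaf <- nleaf + 1L; nn <- nn + 2L
  }
  list(children = children, leafof = leafof, root = 1L, nnode = nn)
}

pda_topology_ <- function(n) {
  children <- vector("list", 2L * n - 1L)
  for (i in seq_along(children)) children[[i]] <- integer(0)
  children[[1L]] <- c(2L, 3L)
  leafof <- c(NA, 1L, 2L, rep(NA, 2L * n - 4L))
  parent <- c(NA, 1L, 1L, rep(NA, 2L * n - 4L))
  nn <- 3L; root <- 1L
  if (n >= 3L) for (j in 3:n) {
    nonroot <- which(seq_len(nn) != root)
    pick <- sample.int(length(nonroot) + 1L, 1L)  # + 1 = the root edge
    newint <- nn + 1L; newleaf <- nn + 2L
    if (pick > length(nonroot)) {
      children[[newint]] <- c(root, newleaf)
      parent[root] <- newint; parent[newint] <- NA
      root <- newint
    } else {
      v <- nonroot[pick]; p <- parent[v]
      children[[p]][children[[p]] == v] <- newint
      children[[newint]] <- c(v, newleaf)
      parent[v] <- newint; parent[newint] <- p
    }
    parent[newleaf] <- newint
    leafof[newleaf] <- j
    nn <- nn + 2L
  }
  list(children = children, leafof = leafof, root = root, nnode = nn)
}
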