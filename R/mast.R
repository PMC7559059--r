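# Exact maximum agreement subtree (MAST) computation.
#
# Agreement is homeomorphic and topology-only: a leaf set S is an agreement
# set when the two trees restricted to S (with unary nodes suppressed) have
# identical topology. mast_rooted() is the dynamic program of the classic
# rooted MAST recursion, exact for polytomies via maximum-weight children
# matching; mast_unrooted() reduces to rooted MAST by rooting both trees at
# each leaf in turn; brute_force_mast() is an exhaustive oracle for small n.

new_mast_result <- function(size, witness, rooted) {
  structure(list(size = as.integer(size), witness = sort(witness),
                 rooted = rooted),
            class = "mast_result")
}

#' @export
print.mast_result <- function(x, ...) {
  cat(if (x$rooted) "Rooted" else "Unrooted",
      " maximum agreement subtree: size ", x$size, "\n", sep = "")
  cat("  witness: ", paste(x$witness, collapse = " "), "\n", sep = "")
  invisible(x)
}

# ---- internal DP machinery --------------------------------------------------

# childlist with leaf ids resolved against a sorted label universe, children
# ordered by smallest descendant label (deterministic backtracking)
prep_tree_ <- function(phy, labs) {
  cl <- as_childlist(phy)
  leafof <- rep(NA_integer_, cl$nnode)
  leafof[seq_len(cl$ntip)] <- match(phy$tip.label, labs)
  po <- integer(0); stack <- cl$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    po <- c(po, v); stack <- c(stack, cl$children[[v]])
  }
  po <- rev(po)
  minlab <- integer(cl$nnode)
  leafset <- matrix(FALSE, cl$nnode, length(labs))
  for (v in po) {
    if (!is.na(leafof[v])) {
      leafset[v, leafof[v]] <- TRUE
      minlab[v] <- leafof[v]
    } else {
      for (c in cl$children[[v]]) leafset[v, ] <- leafset[v, ] | leafset[c, ]
      cl$children[[v]] <- cl$children[[v]][order(minlab[cl$children[[v]]])]
      minlab[v] <- min(minlab[cl$children[[v]]])
    }
  }
  list(children = cl$children, root = cl$root, nnode = cl$nnode,
       leafof = leafof, post = po, leafset = leafset)
}

# maximum-weight (not necessarily perfect) bipartite matching of children by
# subset dynamic programming; returns value and the chosen pairs
match_children_ <- function(W) {
  if (ncol(W) > nrow(W)) {  # keep the subset dimension small
    r <- match_children_(t(W))
    if (!is.null(r$pairs)) r$pairs <- r$pairs[, 2:1, drop = FALSE]
    return(r)
  }
  p <- nrow(W); q <- ncol(W)
  if (p == 2L && q == 2L) {
    s1 <- W[1L, 1L] + W[2L, 2L]; s2 <- W[1L, 2L] + W[2L, 1L]
    if (s1 >= s2) return(list(value = s1, pairs = cbind(1:2, 1:2)))
    return(list(value = s2, pairs = cbind(1:2, 2:1)))
  }
  nS <- bitwShiftL(1L, q)
  f <- matrix(0, p + 1L, nS)
  for (i in seq_len(p)) for (S in 0:(nS - 1L)) {
    best <- f[i, S + 1L]
    for (j in seq_len(q)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, bit) != 0L) {
        cand <- f[i, S - bit + 1L] + W[i, j]
        if (cand > best) best <- cand
      }
    }
    f[i + 1L, S + 1L] <- best
  }
  # recover pairs from the full subset
  pairs <- NULL
  S <- nS - 1L
  for (i in p:1) {
    if (f[i + 1L, S + 1L] == f[i, S + 1L]) next
    for (j in seq_len(q)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, bit) != 0L &&
          f[i + 1L, S + 1L] == f[i, S - bit + 1L] + W[i, j]) {
        pairs <- rbind(pairs, c(i, j))
        S <- S - bit
        break
      }
    }
  }
  list(value = f[p + 1L, nS], pairs = pairs)
}

mast_dp_ <- function(a, b) {
  M <- matrix(0L, a$nnode, b$nnode)
  for (u in a$post) {
    lu <- a$leafof[u]; cu <- a$children[[u]]
    for (v in b$post) {
      lv <- b$leafof[v]; cv <- b$children[[v]]
      if (!is.na(lu) && !is.na(lv)) M[u, v] <- as.integer(lu == lv)
      else if (!is.na(lu)) M[u, v] <- as.integer(b$leafset[v, lu])
      else if (!is.na(lv)) M[u, v] <- as.integer(a$leafset[u, lv])
      else {
        best <- max(M[cu, v], M[u, cv])
        if (length(cu) == 2L && length(cv) == 2L) {
          mm <- max(M[cu[1L], cv[1L]] + M[cu[2L], cv[2L]],
                    M[cu[1L], cv[2L]] + M[cu[2L], cv[1L]])
        } else {
          mm <- match_children_(M[cu, cv, drop = FALSE])$value
        }
        M[u, v] <- max(best, mm)
      }
    }
  }
  M
}

# deterministic witness reconstruction from the DP table
mast_backtrack_ <- function(a, b, M, u, v) {
  target <- M[u, v]
  if (target == 0L) return(integer(0))
  lu <- a$leafof[u]; lv <- b$leafof[v]
  if (!is.na(lu)) return(lu)
  if (!is.na(lv)) return(lv)
  cu <- a$children[[u]]; cv <- b$children[[v]]
  if (length(cu) == 2L && length(cv) == 2L) {
    mm <- max(M[cu[1L], cv[1L]] + M[cu[2L], cv[2L]],
              M[cu[1L], cv[2L]] + M[cu[2L], cv[1L]])
    if (mm == target) {
      if (M[cu[1L], cv[1L]] + M[cu[2L], cv[2L]] == target)
        return(c(mast_backtrack_(a, b, M, cu[1L], cv[1L]),
                 mast_backtrack_(a, b, M, cu[2L], cv[2L])))
      return(c(mast_backtrack_(a, b, M, cu[1L], cv[2L]),
               mast_backtrack_(a, b, M, cu[2L], cv[1L])))
    }
  } else {
    mt <- match_children_(M[cu, cv, drop = FALSE])
    if (mt$value == target) {
      out <- integer(0)
      if (!is.null(mt$pairs)) for (r in seq_len(nrow(mt$pairs)))
        out <- c(out, mast_backtrack_(a, b, M,
                                      cu[mt$pairs[r, 1L]], cv[mt$pairs[r, 2L]]))
      return(out)
    }
  }
  for (c in cu) if (M[c, v] == target) return(mast_backtrack_(a, b, M, c, v))
  for (d in cv) if (M[u, d] == target) return(mast_backtrack_(a, b, M, u, d))
  stop("internal error: MAST backtracking failed")  # nocov
}

# ---- public operations ------------------------------------------------------

#' Rooted maximum agreement subtree
#'
#' Exact rooted homeomorphic MAST by dynamic programming over node pairs.
#' Polytomies are handled exactly through a maximum-weight matching of the
#' children. A witness leaf set of the returned size is reconstructed by
#' deterministic backtracking.
#'
#' @param t1,t2 rooted `phylo` objects on the same leaf set.
#' @param verify check the witness invariant (restrictions topology-equal and
#'   of the returned size)?
#' @return an object of class `mast_result`: `size`, `witness`, `rooted`.
#' @export
mast_rooted <- function(t1, t2, verify = FALSE) {
  validate_tree(t1); validate_tree(t2)
  check_same_leaves(t1, t2)
  labs <- sort(t1$tip.label)
  if (length(labs) == 1L) return(new_mast_result(1L, labs, TRUE))
  a <- prep_tree_(t1, labs); b <- prep_tree_(t2, labs)
  M <- mast_dp_(a, b)
  wit <- labs[sort(mast_backtrack_(a, b, M, a$root, b$root))]
  res <- new_mast_result(M[a$root, b$root], wit, TRUE)
  if (verify) verify_mast_witness(t1, t2, res)
  res
}

#' Unrooted maximum agreement subtree
#'
#' Treats both trees as unrooted and returns the size of the largest leaf set
#' on which the unrooted restrictions agree -- equivalently, the maximum of
#' the rooted MAST over all rootings of both trees. Computed by the standard
#' leaf-rooting reduction: every agreement set contains some leaf x, and
#' agreement sets through x correspond to rooted agreement sets of the two
#' trees rooted at x.
#'
#' @inheritParams mast_rooted
#' @return an object of class `mast_result` with `rooted = FALSE`.
#' @export
mast_unrooted <- function(t1, t2, verify = FALSE) {
  validate_tree(t1); validate_tree(t2)
  check_same_leaves(t1, t2)
  labs <- sort(t1$tip.label)
  n <- length(labs)
  if (n <= 3L) return(new_mast_result(n, labs, FALSE))
  best <- NULL
  for (x in labs) {
    r1 <- root_at_leaf_(t1, x); r2 <- root_at_leaf_(t2, x)
    sub <- sort(setdiff(labs, x))
    a <- prep_childlist_(r1, sub); b <- prep_childlist_(r2, sub)
    M <- mast_dp_(a, b)
    sz <- M[a$root, b$root] + 1L
    if (is.null(best) || sz > best$size) {
      wit <- c(x, sub[sort(mast_backtrack_(a, b, M, a$root, b$root))])
      best <- list(size = sz, witness = wit)
    }
  }
  res <- new_mast_result(best$size, best$witness, FALSE)
  if (verify) verify_mast_witness(t1, t2, res)
  res
}

# root the unrooted topology underlying phy at leaf `x`: returns a childlist
# tree on the remaining leaves whose root is x's former neighbour
root_at_leaf_ <- function(phy, x) {
  n <- length(phy$tip.label)
  root <- n + 1L
  nn <- n + phy$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  if (length(adj[[root]]) == 2L) {  # suppress degree-2 root
    kids <- adj[[root]]
    adj[[kids[1L]]] <- c(setdiff(adj[[kids[1L]]], root), kids[2L])
    adj[[kids[2L]]] <- c(setdiff(adj[[kids[2L]]], root), kids[1L])
    adj[[root]] <- integer(0)
  }
  xi <- match(x, phy$tip.label)
  start <- adj[[xi]]
  children <- vector("list", nn)
  for (i in seq_len(nn)) children[[i]] <- integer(0)
  parent <- rep(NA_integer_, nn)
  parent[start] <- xi
  stack <- start
  while (length(stack)) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (y in adj[[w]]) {
      if (y == parent[w]) next
      children[[w]] <- c(children[[w]], y)
      parent[y] <- w
      stack <- c(stack, y)
    }
  }
  list(children = children, root = start, nnode = nn,
       tip.label = phy$tip.label, dropped = xi)
}

# prep_tree_ analogue for a childlist produced by root_at_leaf_
prep_childlist_ <- function(cl, labs) {
  leafof <- rep(NA_integer_, cl$nnode)
  for (v in seq_len(cl$nnode))
    if (length(cl$children[[v]]) == 0L && v != cl$dropped &&
        v <= length(cl$tip.label))
      leafof[v] <- match(cl$tip.label[v], labs)
  po <- integer(0); stack <- cl$root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    po <- c(po, v); stack <- c(stack, cl$children[[v]])
  }
  po <- rev(po)
  minlab <- rep(.Machine$integer.max, cl$nnode)
  leafset <- matrix(FALSE, cl$nnode, length(labs))
  children <- cl$children
  for (v in po) {
    if (!is.na(leafof[v])) {
      leafset[v, leafof[v]] <- TRUE
      minlab[v] <- leafof[v]
    } else if (length(children[[v]])) {
      for (c in children[[v]]) leafset[v, ] <- leafset[v, ] | leafset[c, ]
      children[[v]] <- children[[v]][order(minlab[children[[v]]])]
      minlab[v] <- min(minlab[children[[v]]])
    }
  }
  list(children = children, root = cl$root, nnode = cl$nnode,
       leafof = leafof, post = po, leafset = leafset)
}

verify_mast_witness <- function(t1, t2, res) {
  check_that(length(res$witness) == res$size,
             "MAST witness size does not match reported size")
  a <- restrict_to_leaves(t1, res$witness)
  b <- restrict_to_leaves(t2, res$witness)
  ok <- if (res$size <= 2L) TRUE else same_topology(a, b, rooted = res$rooted)
  check_that(ok, "MAST witness restrictions are not topology-equal")
  invisible(TRUE)
}

# ---- exhaustive oracle ------------------------------------------------------

# cached bit-count lookup for masks below 2^n (oracle guard keeps n <= 12)
.popcount_cache <- new.env(parent = emptyenv())
popcount_table_ <- function(n) {
  key <- as.character(n)
  if (is.null(.popcount_cache[[key]])) {
    m <- 0:(bitwShiftL(1L, n) - 1L)
    pc <- integer(length(m))
    for (b in 0:(n - 1L)) pc <- pc + (bitwAnd(m, bitwShiftL(1L, b)) != 0L)
    .popcount_cache[[key]] <- pc
  }
  .popcount_cache[[key]]
}

#' Brute-force maximum agreement subtree (test oracle)
#'
#' Enumerates leaf subsets in decreasing size and tests topology equality of
#' the restrictions. Exact but exponential; refuses more than 12 leaves.
#'
#' @inheritParams mast_rooted
#' @param rooted compare restrictions as rooted (clusters) or unrooted
#'   (splits)?
#' @return an object of class `mast_result`.
#' @export
brute_force_mast <- function(t1, t2, rooted = TRUE) {
  validate_tree(t1); validate_tree(t2)
  check_same_leaves(t1, t2)
  labs <- sort(t1$tip.label)
  n <- length(labs)
  check_that(n <= 12L, "brute_force_mast refuses n > 12 leaves")
  cl_masks <- function(phy) {
    pp <- ape::prop.part(phy)
    unique(vapply(pp, function(idx)
      sum(bitwShiftL(1L, match(phy$tip.label[idx], labs) - 1L)), 0L))
  }
  c1 <- cl_masks(t1); c2 <- cl_masks(t2)
  popcount <- popcount_table_(n)
  full <- bitwShiftL(1L, n) - 1L
  sig <- function(cm, S) {
    if (rooted) {
      A <- bitwAnd(cm, S)
      sort(unique(A[popcount[A + 1L] >= 2L]))
    } else {
      A <- bitwAnd(cm, S)
      B <- bitwAnd(S, bitwNot(A))
      keepi <- popcount[A + 1L] >= 2L & popcount[B + 1L] >= 2L
      lowbit <- bitwAnd(S, -S)
      canon <- ifelse(bitwAnd(A, lowbit) != 0L, A, B)
      sort(unique(canon[keepi]))
    }
  }
  masks <- 0:full
  ord <- order(-popcount[masks + 1L], masks)
  for (S in masks[ord]) {
    sz <- popcount[S + 1L]
    if (sz < 1L) next
    if (sz <= 2L || identical(sig(c1, S), sig(c2, S))) {
      wit <- labs[bitwAnd(S, bitwShiftL(1L, 0:(n - 1))) != 0L]
      return(new_mast_result(sz, wit, rooted))
    }
  }
  new_mast_result(1L, labs[1L], rooted)  # nocov
}
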