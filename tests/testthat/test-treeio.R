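test_that("parse_newick handles minimal and nested trees", {
  t2 <- tr("(A,B);")
  expect_setequal(t2$tip.label, c("A", "B"))

  t3 <- tr("((A:1,B:1):1,C:2);")
  expect_setequal(t3$tip.label, c("A", "B", "C"))
  expect_setequal(tree_clusters(t3), c("A|B", "A|B|C"))
  expect_equal(sort(t3$edge.length), c(1, 1, 1, 2))

  t1 <- tr("A;")
  expect_equal(t1$tip.label, "A")
  expect_equal(write_newick(t1), "A;")
})

test_that("malformed Newick is rejected with a position, duplicates with labels", {
  expect_error(parse_newick("(A,B)"), "missing terminating ';'")
  expect_error(parse_newick("((A,B);"), "unclosed")
  expect_error(parse_newick("(A,B));"), "position 6")
  expect_error(parse_newick("(A,(B,A));"), "duplicate leaf labels: A")
})

test_that("write-then-parse round trip preserves topology", {
  for (s in 1:100) {
    t <- random_tree(27, model = if (s %% 2) "yule" else "pda", seed = s)
    expect_true(same_topology(t, parse_newick(write_newick(t))))
  }
  # lengths dropped when requested
  t3 <- tr("((A:1,B:1):1,C:2);")
  expect_false(grepl(":", write_newick(t3, include_lengths = FALSE)))
  expect_true(grepl(":", write_newick(t3)))
})

test_that("read_newick reads one tree per line", {
  f <- tempfile(fileext = ".nwk")
  writeLines(c("(A,(B,C));", "((A,B),C);"), f)
  trees <- read_newick(f)
  expect_length(trees, 2)
  expect_false(same_topology(trees[[1]], trees[[2]]))
  expect_error(read_newick(tempfile()), "not found")
})

test_that("restrict_to_leaves induces the correct topology", {
  t4 <- tr("((A,B),(C,D));")
  r <- restrict_to_leaves(t4, c("A", "C", "D"))
  expect_true(same_topology(r, tr("(A,(C,D));")))
  expect_true(same_topology(restrict_to_leaves(t4, c("A", "B", "C", "D")), t4))
  expect_equal(restrict_to_leaves(t4, "B")$tip.label, "B")
  expect_error(restrict_to_leaves(t4, c("A", "Z")), "Z")
})

test_that("restriction clusters are intersections of source clusters", {
  key <- function(x) paste(sort(x), collapse = "|")
  for (s in 1:20) {
    t <- random_tree(10, "yule", seed = s)
    keep <- sort(sample(t$tip.label, 6))
    expected <- unique(unlist(lapply(strsplit(tree_clusters(t), "\\|"), function(cl) {
      inter <- intersect(cl, keep)
      if (length(inter) >= 2) key(inter)
    })))
    got <- tree_clusters(restrict_to_leaves(t, keep))
    expect_setequal(got, expected[!vapply(expected, is.null, TRUE)])
  }
})

test_that("rerooting covers all placements and is involutive on topology", {
  t3 <- tr("((A,B),C);")
  shapes <- unique(vapply(seq_len(nrow(t3$edge)), function(e)
    paste(sort(tree_clusters(reroot_on_edge(t3, e))), collapse = ";"), ""))
  # 3 rooted triplet shapes on {A,B,C}
  expect_length(shapes, 3)

  t <- random_tree(8, "yule", seed = 42)
  r1 <- reroot_on_edge(t, 5)
  expect_true(same_topology(t, r1, rooted = FALSE))
  r2 <- reroot_on_edge(r1, 3)
  expect_true(same_topology(t, r2, rooted = FALSE))

  cherry <- tr("(A,B);")
  expect_true(same_topology(reroot_on_edge(cherry, 1), cherry))
  expect_error(reroot_on_edge(t, 99), "invalid edge id")
})

test_that("same_topology and rf_distance follow the cluster/split definition", {
  t <- random_tree(12, "pda", seed = 9)
  expect_equal(rf_distance(t, t), 0L)
  expect_true(same_topology(t, t))

  expect_false(same_topology(tr("((A,B),C);"), tr("((A,C),B);")))
  expect_error(rf_distance(tr("(A,B);"), tr("(A,C);")), "leaf sets")

  # hand-enumerated 5-leaf pair:
  # T1 clusters {AB},{CD},{CDE},{ABCDE}; T2 clusters {AB},{ABC},{DE},{ABCDE}
  # shared {AB},{ABCDE} -> rooted RF = 4
  t1 <- tr("((A,B),((C,D),E));")
  t2 <- tr("(((A,B),C),(D,E));")
  expect_equal(rf_distance(t1, t2, rooted = TRUE), 4L)
  # unrooted splits: T1 {AB|CDE},{CD|ABE}; T2 {AB|CDE},{DE|ABC} -> RF = 2
  expect_equal(rf_distance(t1, t2, rooted = FALSE), 2L)
})

test_that("a rooted binary n-leaf tree has n - 1 clusters", {
  for (s in 1:10) {
    n <- sample(4:30, 1)
    t <- random_tree(n, "yule", seed = s)
    expect_length(tree_clusters(t), n - 1L)
  }
})

test_that("random_tree is deterministic and has the requested leaves", {
  t1 <- random_tree(27, "yule", seed = 7)
  t2 <- random_tree(27, "yule", seed = 7)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_length(t1$tip.label, 27)
  expect_error(random_tree(1, "yule", seed = 1), ">= 2")
  expect_false(same_topology(t1, random_tree(27, "yule", seed = 8)))
})

test_that("yule model yields the classical balanced four-leaf shape frequency", {
  # P(balanced rooted shape on 4 leaves) = 1/3 under equal-rates splitting
  balanced <- vapply(1:6000, function(s) {
    t <- random_tree(4, "yule", seed = s)
    sizes <- sort(vapply(strsplit(tree_clusters(t), "\\|"), length, 0L))
    identical(sizes, c(2L, 2L, 4L))
  }, TRUE)
  p_hat <- mean(balanced)
  se <- sqrt(1 / 3 * 2 / 3 / length(balanced))
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
})
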