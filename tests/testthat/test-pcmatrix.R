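test_that("pc_matrix validates counts, ids and codes", {
  m <- pcm(A = c(1L, 2L), B = c(0L, 3L))
  expect_s3_class(m, "pc_matrix")
  expect_equal(attr(m, "category"), "whole_genome")

  bad <- matrix(c(-1L, 2L, 3L, 4L), 2, 2,
                dimnames = list(c("F1", "F2"), c("A", "B")))
  expect_error(pc_matrix(bad), "nonnegative")
  bad2 <- matrix(c(1.5, 2, 3, 4), 2, 2,
                 dimnames = list(c("F1", "F2"), c("A", "B")))
  expect_error(pc_matrix(bad2), "integers")
  bad3 <- matrix(1:4, 2, 2, dimnames = list(c("F1", "F1"), c("A", "B")))
  expect_error(pc_matrix(bad3), "duplicate family ids")
  bad4 <- matrix(1:4, 2, 2, dimnames = list(c("F1", "F2"), c("A", "A")))
  expect_error(pc_matrix(bad4), "duplicate species codes")
})

test_that("TSV round trip and parse errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("family\tMAA\tMAC", "PF00082\t12\t7", "PF00704\t20\t15",
               "PF00089\t3\t0"), f)
  m <- read_pc_matrix(f, category = "proteases")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unclass(m)["PF00704", "MAC"], 15L)
  expect_equal(attr(m, "category"), "proteases")

  # round trip on random matrices
  for (s in 1:5) {
    counts <- matrix(rpois(12, 5), 4, 3,
                     dimnames = list(sprintf("F%d", 1:4), c("AAA", "BBB", "CCC")))
    m0 <- pc_matrix(counts, "cat")
    f2 <- tempfile(fileext = ".tsv")
    write_pc_matrix(m0, f2)
    m1 <- read_pc_matrix(f2, "cat")
    expect_equal(unclass(m1), unclass(m0))
  }

  empty <- tempfile(); writeLines("family\tMAA\tMAC", empty)
  expect_error(read_pc_matrix(empty), "no data rows")
  nonint <- tempfile(); writeLines(c("family\tMAA", "PF1\tx"), nonint)
  expect_error(read_pc_matrix(nonint), "non-integer cell")
  ragged <- tempfile(); writeLines(c("family\tMAA\tMAC", "PF1\t1"), ragged)
  expect_error(read_pc_matrix(ragged), "ragged")
})

test_that("rare-family filter keeps exactly the families above the presence threshold", {
  # presences {1, 2, 3, 5} over 5 species -> 2 survive at the default threshold
  m <- pcm(A = c(1L, 1L, 1L, 1L), B = c(0L, 2L, 1L, 1L), C = c(0L, 0L, 4L, 1L),
           D = c(0L, 0L, 0L, 1L), E = c(0L, 0L, 0L, 1L))
  out <- suppressMessages(filter_rare_families(m))
  expect_equal(rownames(out), c("FAM003", "FAM004"))
  expect_equal(ncol(out), 5L)
  # ubiquitous family retained, idempotent
  expect_equal(unclass(suppressMessages(filter_rare_families(out))), unclass(out))
  # removing everything warns
  m2 <- pcm(A = c(1L, 0L), B = c(0L, 1L), C = c(0L, 0L))
  expect_warning(suppressMessages(filter_rare_families(m2)), "all families removed")
})

test_that("subset_families partitions and validates", {
  m <- pcm(A = 1:4, B = 4:1, C = c(2L, 2L, 2L, 2L))
  parts <- subset_families(m, list(one = c("FAM001", "FAM003"),
                                   two = c("FAM002", "FAM004")))
  expect_named(parts, c("one", "two"))
  expect_equal(attr(parts$one, "category"), "one")
  expect_setequal(c(rownames(parts$one), rownames(parts$two)), rownames(m))
  expect_error(subset_families(m, c("FAM001", "NOPE")), "NOPE")
  expect_error(subset_families(m, character(0)), "empty family set")
})

test_that("correlation distance matches the Pearson definition", {
  # identical columns -> d = 0; reversed -> d = 2
  m <- pcm(A = c(1L, 2L, 3L), B = c(2L, 4L, 6L), C = c(3L, 2L, 1L))
  d <- as.matrix(correlation_distance(m))
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 2)

  # hand evaluation: x = (1,2,3), y = (1,2,4):
  # r = cov/ (sd_x sd_y) = (3/2) / (1 * sqrt(7/3)) = 3*sqrt(3)/(2*sqrt(7))
  m2 <- pcm(A = c(1L, 2L, 3L), B = c(1L, 2L, 4L))
  r_hand <- 3 * sqrt(3) / (2 * sqrt(7))
  expect_equal(as.matrix(correlation_distance(m2))["A", "B"], 1 - r_hand)
  expect_equal(as.matrix(correlation_distance(m2, transform = "half"))["A", "B"],
               (1 - r_hand) / 2)

  # invariance to positive integer rescaling of a species vector
  m3 <- pcm(A = c(1L, 2L, 3L), B = c(1L, 2L, 4L), C = c(9L, 1L, 4L))
  m4 <- pcm(A = c(1L, 2L, 3L), B = 3L * c(1L, 2L, 4L), C = c(9L, 1L, 4L))
  expect_equal(as.matrix(correlation_distance(m3)),
               as.matrix(correlation_distance(m4)))

  expect_error(correlation_distance(pcm(A = c(2L, 2L), B = c(1L, 3L))),
               "zero-variance species column\\(s\\): A")
  expect_error(correlation_distance(pcm(A = 1L, B = 2L)), "at least 2 families")
})
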