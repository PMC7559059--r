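# shared fixture builders

tr <- function(s) parse_newick(s)

# small pc_matrix with given species-count columns
pcm <- function(..., category = "whole_genome", families = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  if (is.null(families)) families <- sprintf("FAM%03d", seq_len(nrow(m)))
  rownames(m) <- families
  pc_matrix(m, category = category)
}

# random symmetric distance matrix without ties (continuous draws)
random_dist <- function(n, seed) {
  with_seed <- icongr:::with_seed
  with_seed(seed, {
    labs <- sprintf("s%02d", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    v <- runif(n * (n - 1) / 2, 0.1, 2)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    m
  })
}
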