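# Seeded generator of protein-content datasets with the statistical
# structure the pipeline assumes: phylogenetic signal along a known species
# tree, lifestyle-convergence enrichment shared by non-sister species, rare
# families hit by the curation filter, and a category partition; plus tree
# pairs of prescribed MAST size for calibration tests.

#' Species codes of the 27-species fungal panel preset
#'
#' Three-letter codes for a cross-phylum fungal panel: model saprophytes,
#' plant/insect/human pathogens, mushrooms, aspergilli, yeasts, and the basal
#' mucoromycete used to root trees. Codes of species not individually named
#' in the underlying study design are synthetic placeholders.
#'
#' @return character vector of 27 codes.
#' @export
fungal_species_codes <- function() {
  c("ROR",                                    # basal mucoromycete (root)
    "UMA", "CNE", "CCI", "LBI", "SCO", "PPL", # basidiomycetes
    "NCR", "AND", "AFU", "AOR", "ANI", "PCH", # sordariomycete/eurotiomycete molds
    "MOR", "FGR", "SSC", "VAL", "BCI",        # ascomycete plant pathogens
    "MAA", "MAC",                             # insect pathogens
    "CIM", "URE",                             # dimorphic human pathogens
    "SCE", "SPO", "CAL", "CGL", "YLI")        # yeasts
}

# lifestyle groups used by the convergence block of the presets
default_lifestyle_groups <- function() {
  list(plant_pathogens = c("MOR", "FGR", "SSC", "VAL", "BCI", "UMA"),
       human_pathogens = c("AFU", "CIM", "CAL", "CNE"),
       insect_pathogens = c("MAA", "MAC"))
}

# category partition: four protein-family categories with study-like sizes,
# ten subcellular categories sharing the remainder
default_category_sizes <- function(n_families) {
  fam <- c(proteases = 49L, CAZy = 64L, ribosomal = 94L, DUF_UPF = 344L)
  check_that(n_families > sum(fam) + 10L,
             "n_families too small for the default category partition")
  sub <- c("cell_wall", "nuclear", "mitochondrial", "cytoplasmic",
           "plasma_membrane", "endoplasmic_reticulum", "golgi",
           "extracellular", "vacuolar", "lysosomal")
  rest <- n_families - sum(fam)
  sizes <- rep(rest %/% 10L, 10L)
  sizes[seq_len(rest %% 10L)] <- sizes[seq_len(rest %% 10L)] + 1L
  names(sizes) <- sub
  c(fam, sizes)
}

#' Simulation configuration
#'
#' Defines the generative model: a Yule species tree with unit root-to-tip
#' height; per-family ancestral copy numbers 1 + Poisson(`ancestral_mean`);
#' per-branch copy dynamics in which each copy survives a branch of length t
#' with probability exp(-loss_rate * t) and the survivors spawn
#' Poisson-distributed new copies so that the expected copy number scales by
#' exp((dup_rate - loss_rate) * t); multiplicative lifestyle-convergence
#' enrichment of a fraction of families; injected rare families present in
#' only 1-2 species; and a category partition covering every family exactly
#' once.
#'
#' @param n_species number of species (leaves of the true tree).
#' @param species species codes (length `n_species`).
#' @param n_families number of evolving families (rare injections excluded).
#' @param tree_model `"yule"` or `"pda"` topology for the true tree.
#' @param tree_height root-to-tip height of the (ultrametric) true tree.
#' @param ancestral_mean Poisson mean of ancestral copy number minus 1.
#' @param dup_rate,loss_rate duplication and loss rates per copy per unit
#'   branch length.
#' @param min_branch minimum internal branch length of the true tree, as a
#'   fraction of `tree_height`; the Yule draw is repeated until satisfied.
#'   Zero (default) accepts any tree; positive values emulate a species
#'   panel chosen so that all divergences are resolvable.
#' @param lifestyle_groups named list of species subsets sharing a lifestyle.
#' @param f_conv fraction of families carrying a convergence block.
#' @param conv_factor enrichment factor gamma (>= 1) applied to convergence
#'   families in their group's species.
#' @param n_rare number of injected rare families (nonzero in 1-2 species).
#' @param category_sizes named integer vector partitioning the
#'   `n_families + n_rare` families into categories; `NULL` for the default
#'   4 + 10 study-like partition.
#' @param seed master seed; every draw derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_species = 27L,
                       species = fungal_species_codes(),
                       n_families = 2000L,
                       tree_model = c("yule", "pda"),
                       tree_height = 1,
                       ancestral_mean = 2,
                       dup_rate = 0.1,
                       loss_rate = 0.1,
                       min_branch = 0,
                       lifestyle_groups = default_lifestyle_groups(),
                       f_conv = 0.15,
                       conv_factor = 2,
                       n_rare = 50L,
                       category_sizes = NULL,
                       seed = 1L) {
  tree_model <- match.arg(tree_model)
  check_that(n_species >= 4, "'n_species' must be >= 4")
  check_that(length(species) == n_species && !anyDuplicated(species),
             "'species' must be n_species distinct codes")
  check_that(n_families >= 2, "'n_families' must be >= 2")
  check_that(tree_height > 0, "'tree_height' must be positive")
  check_that(dup_rate >= 0 && loss_rate >= 0, "rates must be nonnegative")
  check_that(min_branch >= 0 && min_branch < 0.5, "'min_branch' must be in [0, 0.5)")
  check_that(conv_factor >= 1, "'conv_factor' must be >= 1")
  check_that(f_conv >= 0 && f_conv <= 1, "'f_conv' must be in [0, 1]")
  check_that(n_rare >= 0, "'n_rare' must be nonnegative")
  for (g in names(lifestyle_groups))
    check_that(all(lifestyle_groups[[g]] %in% species),
               paste0("lifestyle group '", g, "' contains unknown species"))
  total <- n_families + n_rare
  if (is.null(category_sizes)) category_sizes <- default_category_sizes(total)
  check_that(!is.null(names(category_sizes)) && all(nzchar(names(category_sizes))) &&
               !anyDuplicated(names(category_sizes)),
             "'category_sizes' must have unique names")
  if (sum(category_sizes) != total)
    stop("'category_sizes' must sum to n_families + n_rare = ", total,
         call. = FALSE)
  structure(list(n_species = as.integer(n_species), species = species,
                 n_families = as.integer(n_families), tree_model = tree_model,
                 tree_height = tree_height, ancestral_mean = ancestral_mean,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 min_branch = min_branch,
                 lifestyle_groups = lifestyle_groups, f_conv = f_conv,
                 conv_factor = conv_factor, n_rare = as.integer(n_rare),
                 category_sizes = category_sizes, seed = as.integer(seed)),
            class = "sim_config")
}

#' Named simulation presets
#'
#' `"paper_like"`: the default study-scale conditions (27 species, 2000
#' families, moderate gain/loss, moderate lifestyle convergence, no
#' branch-length constraint) -- a messy, lifestyle-dominated regime in which
#' phenograms are not expected to match the true tree.
#' `"low_noise"`: strong divergence signal relative to sampling noise
#' (higher per-copy turnover, larger ancestral families, resolvable internal
#' branches) and no convergence, so the whole-genome phenogram recovers the
#' true tree topology in nearly all replicates.
#' `"strong_convergence"`: the low-noise dynamics plus a strong convergence
#' block (gamma = 3 on a quarter of the families), which pulls lifestyle
#' groups together in the phenogram.
#'
#' @param name preset name.
#' @param seed master seed.
#' @return a [sim_config].
#' @export
sim_preset <- function(name = c("paper_like", "low_noise", "strong_convergence"),
                       seed = 1L) {
  name <- match.arg(name)
  switch(name,
    paper_like = sim_config(seed = seed),
    low_noise = sim_config(dup_rate = 0.3, loss_rate = 0.15,
                           ancestral_mean = 5, min_branch = 0.04,
                           f_conv = 0, conv_factor = 1, seed = seed),
    strong_convergence = sim_config(dup_rate = 0.3, loss_rate = 0.15,
                                    ancestral_mean = 5, min_branch = 0.04,
                                    f_conv = 0.25, conv_factor = 3, seed = seed))
}

# ultrametric Yule tree with heights: grow by splitting a random pending
# lineage at exponential waiting times, rescale to the requested height
yule_tree_lengths_ <- function(n, height) {
  children <- vector("list", 2L * n - 1L)
  for (i in seq_along(children)) children[[i]] <- integer(0)
  children[[1L]] <- c(2L, 3L)
  leafof <- c(NA, 1L, 2L, rep(NA, 2L * n - 4L))
  btime <- c(0, 0, 0)  # birth time of each node
  leaves <- c(2L, 3L); nleaf <- 2L; nn <- 3L; t <- 0
  while (nleaf < n) {
    t <- t + stats::rexp(1L, rate = nleaf)
    j <- sample.int(length(leaves), 1L)
    v <- leaves[j]
    a <- nn + 1L; b <- nn + 2L
    children[[v]] <- c(a, b)
    leafof[a] <- leafof[v]; leafof[b] <- nleaf + 1L; leafof[v] <- NA
    btime[a] <- t; btime[b] <- t
    leaves[j] <- a; leaves <- c(leaves, b)
    nleaf <- nleaf + 1L; nn <- nn + 2L
  }
  present <- t + stats::rexp(1L, rate = nleaf)
  scale <- height / present
  # branch length of node v = (birth time of its children or present) - birth
  blen <- numeric(nn)
  for (v in seq_len(nn)) {
    end <- if (length(children[[v]])) btime[children[[v]][1L]] else present
    blen[v] <- (end - btime[v]) * scale
  }
  blen[1L] <- NA  # root has no branch
  list(children = children, leafof = leafof, root = 1L, nnode = nn,
       blen = blen)
}

#' Simulate a protein-content dataset
#'
#' Draws the true species tree, evolves integer family counts along it under
#' the configured gain/loss dynamics, applies the convergence block, injects
#' rare families, and partitions families into category matrices. Evolving
#' families are conditioned (by per-family re-draws) on being present in at
#' least 3 species, so the injected rare families are exactly the families
#' the default curation filter removes. Fully determined by the master seed.
#'
#' @param cfg a [sim_config].
#' @return an object of class `pc_simulation`: `tree` (true species tree,
#'   `phylo`), `matrices` (named list: `whole_genome` plus one [pc_matrix]
#'   per category), `family_category` (named character), `config`.
#' @export
simulate_pc_dataset <- function(cfg) {
  check_that(inherits(cfg, "sim_config"), "'cfg' must be a sim_config")
  if (cfg$dup_rate == 0 && cfg$loss_rate == 0 && cfg$conv_factor == 1)
    warning("degenerate configuration: all species will have identical counts ",
            "(zero-variance columns; the pipeline will reject them)",
            call. = FALSE)
  with_seed(cfg$seed, {
    S <- cfg$n_species; F <- cfg$n_families
    # true species tree
    if (cfg$tree_model == "yule") {
      draws <- 0L
      repeat {
        tr <- yule_tree_lengths_(S, cfg$tree_height)
        draws <- draws + 1L
        if (cfg$min_branch == 0) break
        internal <- which(is.na(tr$leafof) & !is.na(tr$blen))
        if (min(tr$blen[internal]) >= cfg$min_branch * cfg$tree_height) break
        if (draws >= 10000L)
          stop("could not draw a Yule tree with min_branch = ", cfg$min_branch,
               " within 10000 attempts; lower 'min_branch'", call. = FALSE)
      }
    } else {
      tr <- pda_topology_(S)
      tr$blen <- c(NA, rep(cfg$tree_height / max(2, ceiling(log2(S))),
                           tr$nnode - 1L))
    }
    perm <- sample.int(S)
    labs <- character(tr$nnode)
    isleaf <- !is.na(tr$leafof)
    labs[isleaf] <- cfg$species[perm[tr$leafof[isleaf]]]
    tree <- parse_newick(childlist_newick(tr$children, tr$root, labs,
                                          lengths = tr$blen))
    # preorder edge walk (vectorized across families)
    evolve <- function(anc) {
      counts <- matrix(0L, length(anc), tr$nnode)
      counts[, tr$root] <- anc
      stack <- tr$root
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (c in tr$children[[v]]) {
          t <- tr$blen[c]
          surv <- stats::rbinom(length(anc), counts[, v],
                                exp(-cfg$loss_rate * t))
          born <- stats::rpois(length(anc), surv * (exp(cfg$dup_rate * t) - 1))
          counts[, c] <- surv + born
          stack <- c(stack, c)
        }
      }
      counts[, which(isleaf)[order(match(labs[isleaf], cfg$species))], drop = FALSE]
    }
    anc <- 1L + stats::rpois(F, cfg$ancestral_mean)
    leafcounts <- evolve(anc)  # families x species, columns in cfg$species order
    colnames(leafcounts) <- cfg$species
    # condition evolving families on presence in >= 3 species
    tries <- 0L
    repeat {
      low <- which(rowSums(leafcounts > 0L) < 3L)
      if (!length(low) || tries >= 100L) break
      leafcounts[low, ] <- evolve(anc[low])
      tries <- tries + 1L
    }
    if (length(which(rowSums(leafcounts > 0L) < 3L)))
      warning("some evolving families remained present in < 3 species after ",
              "re-draws (loss rate too high?)", call. = FALSE)
    # convergence block: multiplicative enrichment per family in one group
    n_conv <- round(cfg$f_conv * F)
    if (n_conv > 0 && length(cfg$lifestyle_groups) > 0 && cfg$conv_factor > 1) {
      conv_fams <- sample.int(F, n_conv)
      grp <- sample(names(cfg$lifestyle_groups), n_conv, replace = TRUE)
      for (i in seq_len(n_conv)) {
        sp <- cfg$lifestyle_groups[[grp[i]]]
        leafcounts[conv_fams[i], sp] <-
          as.integer(round(leafcounts[conv_fams[i], sp] * cfg$conv_factor))
      }
    }
    # rare families: nonzero in only 1-2 species
    rare <- matrix(0L, cfg$n_rare, S, dimnames = list(NULL, cfg$species))
    if (cfg$n_rare > 0) for (i in seq_len(cfg$n_rare)) {
      k <- sample(1:2, 1L)
      sp <- sample.int(S, k)
      rare[i, sp] <- 1L + stats::rpois(k, 1)
    }
    counts <- rbind(leafcounts, rare)
    total <- F + cfg$n_rare
    rownames(counts) <- sprintf("FAM%05d", seq_len(total))
    rare_ids <- rownames(counts)[seq_len(cfg$n_rare) + F]
    # category partition over all families
    cat_names <- names(cfg$category_sizes)
    assignment <- sample(rep(cat_names, times = cfg$category_sizes))
    names(assignment) <- rownames(counts)
    whole <- pc_matrix(counts, "whole_genome")
    mats <- c(list(whole_genome = whole),
              lapply(stats::setNames(cat_names, cat_names), function(cn)
                subset_families(whole, names(assignment)[assignment == cn],
                                category = cn)))
    structure(list(tree = tree, matrices = mats,
                   family_category = assignment, rare_ids = rare_ids,
                   config = cfg),
              class = "pc_simulation")
  })
}

#' @export
print.pc_simulation <- function(x, ...) {
  cfg <- x$config
  cat("Simulated protein-content dataset: ", cfg$n_species, " species, ",
      cfg$n_families, " evolving + ", cfg$n_rare, " rare families, ",
      length(x$matrices), " matrices (whole genome + ",
      length(x$matrices) - 1L, " categories), seed ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Construct a tree pair with prescribed rooted MAST size
#'
#' Builds a shared random core subtree on k leaves, attaches the remaining
#' n - k leaves in deliberately conflicting positions (stacked above the core
#' root in one tree, scattered inside the core in the other), and verifies
#' the exact rooted MAST size with [mast_rooted], re-sampling on the seed
#' stream until the verified size equals k.
#'
#' @param n total leaf count (>= 3).
#' @param k target rooted MAST size, 2 <= k <= n.
#' @param seed integer seed.
#' @param labels optional n distinct leaf labels.
#' @param max_tries re-sampling limit before giving up.
#' @return list of class `mast_pair`: `t1`, `t2`, `k`, `witness` (the core
#'   leaf set, a certificate of agreement).
#' @export
make_tree_pair_with_mast <- function(n, k, seed, labels = NULL,
                                     max_tries = 200L) {
  check_that(n >= 3 && k >= 2 && k <= n, "need 3 <= n and 2 <= k <= n")
  n <- as.integer(n); k <- as.integer(k)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n))
  check_that(length(labels) == n && !anyDuplicated(labels),
             "'labels' must be n distinct strings")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      core_labs <- sort(sample(labels, k))
      extras <- setdiff(labels, core_labs)
      core <- random_tree(max(k, 2L), "yule", seed = sample.int(2^30, 1L),
                          labels = core_labs)
      if (k == n) return(structure(list(t1 = core, t2 = core, k = k,
                                        witness = core_labs),
                                   class = "mast_pair"))
      core_nwk <- sub(";$", "", write_newick(core, include_lengths = FALSE))
      # t1: extras stacked above the core root (ascending caterpillar)
      s1 <- core_nwk
      for (x in sample(extras)) s1 <- paste0("(", s1, ",", x, ")")
      t1 <- parse_newick(paste0(s1, ";"))
      # t2: each extra attached to a random non-root edge inside the core
      cl <- as_childlist(core)
      children <- cl$children; root <- cl$root
      labs2 <- character(cl$nnode)
      labs2[seq_len(cl$ntip)] <- core$tip.label
      parent <- rep(NA_integer_, cl$nnode)
      for (v in seq_len(cl$nnode)) for (c in children[[v]]) parent[c] <- v
      for (x in sample(extras)) {
        nonroot <- which(seq_along(children) != root)
        v <- nonroot[sample.int(length(nonroot), 1L)]
        p <- parent[v]
        newint <- length(children) + 1L
        newleaf <- length(children) + 2L
        children[[newint]] <- c(v, newleaf)
        children[[newleaf]] <- integer(0)
        children[[p]][children[[p]] == v] <- newint
        parent[v] <- newint; parent[newint] <- p; parent[newleaf] <- newint
        labs2[newint] <- ""; labs2[newleaf] <- x
      }
      t2 <- parse_newick(childlist_newick(children, root, labs2))
      res <- mast_rooted(t1, t2)
      if (res$size == k)
        return(structure(list(t1 = t1, t2 = t2, k = k, witness = core_labs),
                         class = "mast_pair"))
    }
    stop("could not realise MAST size ", k, " for n = ", n, " within ",
         max_tries, " attempts", call. = FALSE)
  })
}

#' Tree-recovery and monophyly experiment on simulated data
#'
#' For each replicate: simulate a dataset, curate the whole-genome matrix,
#' build the UPGMA phenogram from correlation distances, and record whether
#' it matches the true tree topology (unrooted Robinson-Foulds distance 0)
#' and whether each lifestyle group is monophyletic in the phenogram.
#'
#' @param cfg a [sim_config]; per-replicate seeds derive from `seed`.
#' @param replicates number of replicates (>= 1).
#' @param seed integer seed for the replicate stream.
#' @return list of class `recovery_summary`: `recovery_fraction`,
#'   `monophyly_fraction` (named by group), `details` data.frame.
#' @export
recovery_experiment <- function(cfg, replicates = 20L, seed = 1L) {
  check_that(inherits(cfg, "sim_config"), "'cfg' must be a sim_config")
  check_that(replicates >= 1, "'replicates' must be >= 1")
  seeds <- with_seed(seed, sample.int(2^30, replicates))
  groups <- cfg$lifestyle_groups
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    sim <- simulate_pc_dataset(cfg_i)
    m <- filter_rare_families(sim$matrices$whole_genome, quiet = TRUE)
    phen <- upgma(correlation_distance(m))
    rf <- rf_distance(phen, sim$tree, rooted = FALSE)
    mono <- vapply(groups, function(sp)
      ape::is.monophyletic(phen, sp), TRUE)
    rows[[i]] <- data.frame(replicate = i, seed = seeds[i], rf = rf,
                            recovered = rf == 0L,
                            t(as.matrix(mono)), stringsAsFactors = FALSE)
  }
  details <- do.call(rbind, rows)
  mono_frac <- if (length(groups))
    colMeans(details[, names(groups), drop = FALSE]) else numeric(0)
  structure(list(recovery_fraction = mean(details$recovered),
                 monophyly_fraction = mono_frac,
                 details = details),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Recovery experiment over ", nrow(x$details), " replicates\n", sep = "")
  cat("  true-tree recovery fraction (RF = 0): ",
      format(x$recovery_fraction), "\n", sep = "")
  for (g in names(x$monophyly_fraction))
    cat("  monophyly of ", g, ": ", format(x$monophyly_fraction[[g]]), "\n",
        sep = "")
  invisible(x)
}
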