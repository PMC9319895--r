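# Synthetic SNP matrices with hierarchical population structure
#
# Allele frequencies drift down a rooted population tree under a
# Balding-Nichols style Beta model: a branch with drift parameter F in (0,1)
# turns the parental frequency p into a draw from
# Beta(p(1-F)/F, (1-p)(1-F)/F), so E[p_child] = p and Var = F p(1-p).

#' Specify a population-split model for SNP simulation
#'
#' @param tree a rooted [ape::phylo] tree (or a newick string) whose branch
#'   lengths carry the per-branch drift parameter F, strictly inside (0,1).
#'   Tip labels name the populations (taxa).
#' @param n_individuals diploid individuals per tip; scalar or named vector.
#' @param n_sites number of biallelic SNP sites.
#' @param missing_rate probability in `[0,1)` that a call is masked missing.
#' @param seed integer seed.
#' @return an object of class `species_model`.
#' @export
species_model <- function(tree, n_individuals, n_sites,
                          missing_rate = 0, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree branches must carry drift F")
  bad <- which(!is.finite(tree$edge.length) |
                 tree$edge.length <= 0 | tree$edge.length >= 1)
  if (length(bad)) {
    stop(sprintf(paste0("drift parameter F must lie strictly in (0,1); ",
                        "offending branch(es) to node(s): %s"),
                 paste(tree$edge[bad, 2], collapse = ", ")))
  }
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  tips <- tree$tip.label
  if (length(n_individuals) == 1L && is.null(names(n_individuals))) {
    n_individuals <- setNames(rep(n_individuals, length(tips)), tips)
  }
  n_individuals <- n_individuals[tips]
  if (any(is.na(n_individuals)) || any(n_individuals < 1)) {
    stop("n_individuals must be >= 1 for every tip")
  }
  if (n_sites < 1) stop("n_sites must be positive")
  stopifnot_scalar_prob(missing_rate, "missing_rate", closed_right = FALSE)
  structure(list(tree = tree, n_individuals = n_individuals,
                 n_sites = as.integer(n_sites),
                 missing_rate = missing_rate, seed = seed),
            class = "species_model")
}

#' Simulate a structured SNP matrix
#'
#' Per site the ancestral frequency is drawn uniformly on `[0.05, 0.95]`,
#' drifts down the model tree, and diploid genotypes are drawn
#' Binomial(2, p_tip) per individual, then encoded as homozygote base /
#' IUPAC heterozygote characters with independent missing masking.
#'
#' @param model a [species_model].
#' @return a [snp_matrix]; the true population of each sample is in its
#'   taxon label (`<tip>_<k>` sample ids, taxon = tip label).
#' @export
simulate_snp_matrix <- function(model) {
  stopifnot(inherits(model, "species_model"))
  with_seed(model$seed, {
    tree <- model$tree
    n_sites <- model$n_sites
    n_tip <- length(tree$tip.label)
    n_node <- max(tree$edge)
    freq <- matrix(NA_real_, nrow = n_node, ncol = n_sites)
    root <- n_tip + 1L
    freq[root, ] <- runif(n_sites, 0.05, 0.95)
    # preorder (cladewise) traversal: parents before children
    ro <- ape::reorder.phylo(tree, "cladewise")
    edge <- ro$edge
    lens <- ro$edge.length
    for (e in seq_len(nrow(edge))) {
      parent <- edge[e, 1]; child <- edge[e, 2]; f <- lens[e]
      p <- freq[parent, ]
      a <- p * (1 - f) / f
      b <- (1 - p) * (1 - f) / f
      if (any(!is.finite(a)) || any(!is.finite(b))) {
        stop(sprintf("non-finite Beta parameters on branch to node %d", child))
      }
      # clamp away from the boundary so deeper branches keep finite Beta shapes
      freq[child, ] <- pmin(pmax(rbeta(n_sites, a, b), 1e-9), 1 - 1e-9)
    }
    # per-site reference/alternate bases
    ref <- sample.int(4L, n_sites, replace = TRUE)
    alt <- ((ref - 1L + sample.int(3L, n_sites, replace = TRUE)) %% 4L) + 1L
    ids <- character(0); taxa <- character(0)
    rows <- list()
    for (t in seq_len(n_tip)) {
      tip <- tree$tip.label[t]
      nt <- model$n_individuals[[tip]]
      p_tip <- freq[t, ]
      dose <- matrix(rbinom(nt * n_sites, 2L, rep(p_tip, each = nt)),
                     nrow = nt)  # count of alt alleles
      a1 <- ifelse(dose >= 1L, alt[col(dose)], ref[col(dose)])
      a2 <- ifelse(dose == 2L, alt[col(dose)], ref[col(dose)])
      codes <- genotype_code(a1, a2)
      dim(codes) <- dim(dose)
      rows[[t]] <- codes
      ids <- c(ids, sprintf("%s_%d", tip, seq_len(nt)))
      taxa <- c(taxa, rep(tip, nt))
    }
    codes <- do.call(rbind, rows)
    if (model$missing_rate > 0) {
      mask <- matrix(runif(length(codes)) < model$missing_rate, nrow = nrow(codes))
      codes[mask] <- "N"
    }
    rownames(codes) <- ids
    snp_matrix(codes, taxa)
  })
}

#' Inject an F1-like hybrid individual into a SNP matrix
#'
#' The new sample draws, per site, one allele from each parent taxon's
#' empirical allele frequencies (an exact F1 at the default
#' `fraction_a = 0.5`); other fractions draw each allele's source taxon
#' independently with probability `fraction_a` for `parent_a`.
#'
#' @param m a [snp_matrix].
#' @param parent_a,parent_b taxon labels present in `m`.
#' @param label sample id for the hybrid (its taxon label is
#'   `"hybrid"` unless `taxon` is given).
#' @param seed integer seed.
#' @param fraction_a expected genome fraction contributed by `parent_a`.
#' @param taxon taxon label to assign to the new sample.
#' @return a [snp_matrix] with one extra sample; original samples unchanged.
#' @export
inject_hybrid <- function(m, parent_a, parent_b, label = "hybrid1",
                          seed = 1L, fraction_a = 0.5, taxon = "hybrid") {
  stopifnot(inherits(m, "snp_matrix"))
  for (p in c(parent_a, parent_b)) {
    if (!any(m$taxon == p)) stop("unknown parent taxon: ", p)
  }
  if (label %in% m$sample_ids) stop("sample id already present: ", label)
  al <- snp_alleles(m)
  n_sites <- ncol(m$codes)
  emp_freq <- function(tx) {
    rows <- which(m$taxon == tx)
    # per site empirical frequency of each of the 4 bases
    f <- matrix(0, nrow = 4L, ncol = n_sites)
    for (s in seq_len(n_sites)) {
      a <- c(al$a1[rows, s], al$a2[rows, s])
      a <- a[!is.na(a)]
      if (!length(a)) a <- 1L  # degenerate: all-missing site, arbitrary base
      f[, s] <- tabulate(a, 4L) / length(a)
    }
    f
  }
  fa <- emp_freq(parent_a)
  fb <- emp_freq(parent_b)
  draw <- function(f) {
    # one allele per site from per-site base frequencies
    u <- runif(n_sites)
    cum <- apply(f, 2, cumsum)
    1L + colSums(cum < rep(u, each = 4L))
  }
  hyb <- with_seed(seed, {
    if (identical(fraction_a, 0.5)) {
      cbind(draw(fa), draw(fb))
    } else {
      src_a1 <- runif(n_sites) < fraction_a
      src_a2 <- runif(n_sites) < fraction_a
      x1 <- draw(fa); y1 <- draw(fb)
      x2 <- draw(fa); y2 <- draw(fb)
      cbind(ifelse(src_a1, x1, y1), ifelse(src_a2, x2, y2))
    }
  })
  code <- genotype_code(hyb[, 1], hyb[, 2])
  codes <- rbind(m$codes, matrix(code, nrow = 1L, dimnames = list(label)))
  snp_matrix(codes, c(m$taxon, setNames(taxon, label)))
}
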