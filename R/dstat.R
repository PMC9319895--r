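# Patterson's D (ABBA-BABA) screening of individuals for hybrid origin

#' Specify a single ABBA-BABA test
#'
#' @param p1,p2,p3 sample ids: `p1`,`p2` the (putative sister) pair, `p3`
#'   the candidate donor lineage.
#' @param outgroup a taxon label (its per-site majority consensus polarizes
#'   the alleles) or a single sample id.
#' @param n_bootstrap bootstrap resamples of sites for the significance
#'   (default 1000).
#' @param seed integer seed.
#' @return an object of class `dtest_spec`.
#' @export
dtest_spec <- function(p1, p2, p3, outgroup, n_bootstrap = 1000, seed = 1L) {
  roles <- c(p1, p2, p3, outgroup)
  if (anyDuplicated(roles)) stop("the four roles must be distinct")
  structure(list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                 n_bootstrap = as.integer(n_bootstrap), seed = seed),
            class = "dtest_spec")
}

# alleles + outgroup-consensus cache shared across the tests of one screen
.dstat_cache <- function(m, outgroup) {
  al <- snp_alleles(m)
  out_rows <- if (outgroup %in% m$sample_ids) {
    match(outgroup, m$sample_ids)
  } else {
    rows <- which(m$taxon == outgroup)
    if (!length(rows)) stop("unknown outgroup: ", outgroup)
    rows
  }
  oa <- rbind(al$a1[out_rows, , drop = FALSE], al$a2[out_rows, , drop = FALSE])
  counts <- vapply(1:4, function(b) colSums(oa == b, na.rm = TRUE),
                   numeric(ncol(oa)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  mx <- apply(counts, 1, max)
  n_at_max <- rowSums(counts == mx)
  anc <- max.col(counts, ties.method = "first")
  anc[mx == 0 | n_at_max > 1L] <- NA_integer_  # all-missing or tied consensus
  list(al = al, anc = anc)
}

# derived-allele frequency matrix (3 x retained sites) for one test spec;
# attr "keep" carries the retained site indices
.dstat_site_freqs <- function(m, spec, cache = NULL) {
  if (is.null(cache)) cache <- .dstat_cache(m, spec$outgroup)
  anc <- cache$anc
  idx <- match(c(spec$p1, spec$p2, spec$p3), m$sample_ids)
  if (anyNA(idx)) stop("unknown sample id in test spec")
  a1 <- cache$al$a1[idx, , drop = FALSE]
  a2 <- cache$al$a2[idx, , drop = FALSE]
  ns <- ncol(a1)
  complete <- !is.na(anc) & colSums(is.na(a1)) == 0L
  # base presence across the three ingroup samples plus the outgroup allele
  pres <- matrix(FALSE, 4L, ns)
  for (b in 1:4) {
    pres[b, ] <- (colSums(a1 == b, na.rm = TRUE) +
                    colSums(a2 == b, na.rm = TRUE)) > 0
  }
  ok_anc <- !is.na(anc)
  pres[cbind(anc[ok_anc], which(ok_anc))] <- TRUE
  n_alleles <- colSums(pres)
  bial <- complete & n_alleles == 2L
  der <- colSums(pres * (1:4)) - ifelse(is.na(anc), 0L, anc)
  keep <- which(bial & der > 0L)
  if (!length(keep)) return(NULL)
  dv <- rep(der[keep], each = 3L)
  dfreq <- (matrix((a1[, keep, drop = FALSE] == dv) +
                     (a2[, keep, drop = FALSE] == dv), nrow = 3L)) / 2
  attr(dfreq, "keep") <- keep
  dfreq
}

#' Patterson's D statistic for one sample triplet plus outgroup
#'
#' Per retained biallelic site, with derived-allele frequencies `p1..p3`
#' polarized by the outgroup consensus (the outgroup frequency is 0 by
#' construction), `abba += (1-p1) p2 p3` and `baba += p1 (1-p2) p3`;
#' `D = (abba - baba) / (abba + baba)`. Significance by bootstrap
#' resampling of sites (or loci when `locus_ids` are given),
#' `Z = D / sd(D_boot)` and a two-sided normal p-value. A test with
#' `abba + baba = 0` has undefined D and is reported non-significant.
#'
#' @param m a [snp_matrix].
#' @param spec a [dtest_spec].
#' @param locus_ids optional vector (one entry per site of `m`) naming the
#'   RAD locus of each site; the bootstrap then resamples loci, respecting
#'   linkage within a locus.
#' @param cache internal: precomputed allele/outgroup cache.
#' @param boot_weights optional pre-drawn site-resampling plan: an
#'   `n_sites x n_bootstrap` multinomial count matrix over all sites of
#'   `m`. [dstat_screen()] draws one such plan per screen and shares it
#'   across its tests; sites a test does not retain simply carry no
#'   contribution.
#' @return an object of class `dstat_result` with fields `abba`, `baba`,
#'   `D`, `bootstrap_sd`, `Z`, `p`, `n_sites`, `undefined`.
#' @export
pattersons_d <- function(m, spec, locus_ids = NULL, cache = NULL,
                         boot_weights = NULL) {
  dfreq <- .dstat_site_freqs(m, spec, cache)
  if (is.null(dfreq)) stop("no informative sites for the test")
  abba_s <- (1 - dfreq[1, ]) * dfreq[2, ] * dfreq[3, ]
  baba_s <- dfreq[1, ] * (1 - dfreq[2, ]) * dfreq[3, ]
  abba <- sum(abba_s); baba <- sum(baba_s)
  undefined <- (abba + baba) == 0
  D <- if (undefined) NA_real_ else (abba - baba) / (abba + baba)
  ns <- length(abba_s)
  boot_sd <- NA_real_; Z <- NA_real_; p <- 1
  if (!undefined && (spec$n_bootstrap > 0 || !is.null(boot_weights))) {
    if (!is.null(boot_weights) && is.null(locus_ids)) {
      w <- boot_weights[attr(dfreq, "keep"), , drop = FALSE]
      num <- crossprod(w, abba_s - baba_s)
      den <- crossprod(w, abba_s + baba_s)
      boot <- as.numeric(ifelse(den > 0, num / den, NA_real_))
    } else {
      if (is.null(locus_ids)) {
        agg_abba <- abba_s; agg_baba <- baba_s
      } else {
        unit <- as.integer(factor(locus_ids[attr(dfreq, "keep")]))
        agg_abba <- as.numeric(rowsum(abba_s, unit))
        agg_baba <- as.numeric(rowsum(baba_s, unit))
      }
      nu <- length(agg_abba)
      boot <- with_seed(spec$seed, {
        w <- stats::rmultinom(spec$n_bootstrap, nu, rep(1 / nu, nu))
        num <- crossprod(w, agg_abba - agg_baba)
        den <- crossprod(w, agg_abba + agg_baba)
        as.numeric(ifelse(den > 0, num / den, NA_real_))
      })
    }
    boot_sd <- stats::sd(boot, na.rm = TRUE)
    if (is.finite(boot_sd) && boot_sd > 0) {
      Z <- D / boot_sd
      p <- 2 * stats::pnorm(-abs(Z))
    } else {
      Z <- if (D == 0) 0 else sign(D) * Inf
      p <- if (D == 0) 1 else 0
    }
  }
  structure(list(spec = spec, abba = abba, baba = baba, D = D,
                 bootstrap_sd = boot_sd, Z = Z, p = p,
                 n_sites = ns, undefined = undefined),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D((%s,%s),%s | %s): D=%.4f Z=%.2f p=%.3g (%d sites)\n",
              x$spec$p1, x$spec$p2, x$spec$p3, x$spec$outgroup,
              x$D, x$Z, x$p, x$n_sites))
  invisible(x)
}

#' Enumerate ABBA-BABA test specs over focal taxa
#'
#' For every unordered pair of focal taxa (A, B): every unordered pair of
#' distinct individuals of A as `{p1, p2}` with every individual of B as
#' `p3`, plus the mirrored specs with the pair in B and `p3` in A. The
#' outgroup role is the designated outgroup taxon (consensus).
#'
#' @param labels named character vector mapping sample id to taxon.
#' @param focal_taxa character vector of focal taxon labels.
#' @param outgroup outgroup taxon label (must not be focal).
#' @param n_bootstrap,seed passed to each [dtest_spec()]; each spec gets its
#'   own seed derived from `seed`.
#' @return list of [dtest_spec] objects.
#' @export
enumerate_triplets <- function(labels, focal_taxa, outgroup,
                               n_bootstrap = 1000, seed = 1L) {
  if (outgroup %in% focal_taxa) stop("outgroup must be disjoint from focal taxa")
  focal_taxa <- unique(focal_taxa)
  specs <- list()
  small <- focal_taxa[vapply(focal_taxa, function(t) sum(labels == t), 0L) < 2L]
  if (length(small)) {
    warning("taxa with < 2 individuals contribute no within-taxon pairs: ",
            paste(small, collapse = ", "))
  }
  if (length(focal_taxa) >= 2L) {
    for (i in seq_len(length(focal_taxa) - 1L)) {
      for (j in (i + 1L):length(focal_taxa)) {
        for (pair_taxon in c(focal_taxa[i], focal_taxa[j])) {
          p3_taxon <- setdiff(c(focal_taxa[i], focal_taxa[j]), pair_taxon)
          ids_pair <- names(labels)[labels == pair_taxon]
          ids_p3 <- names(labels)[labels == p3_taxon]
          if (length(ids_pair) < 2L || !length(ids_p3)) next
          cmb <- utils::combn(ids_pair, 2L)
          for (c in seq_len(ncol(cmb))) {
            for (p3 in ids_p3) {
              specs[[length(specs) + 1L]] <-
                dtest_spec(cmb[1, c], cmb[2, c], p3, outgroup,
                           n_bootstrap = n_bootstrap)
            }
          }
        }
      }
    }
  }
  if (length(specs)) {
    seeds <- derive_seeds(seed, length(specs))
    for (i in seq_along(specs)) specs[[i]]$seed <- seeds[i]
  }
  specs
}

#' Bonferroni-corrected ABBA-BABA screen for hybrid individuals
#'
#' Runs every enumerated test, Bonferroni-corrects over the number of tests
#' executed, and flags as hybrid the introgressed-candidate member of each
#' significant pair: `p2` when `D > 0` (excess sharing of `p2` with `p3`),
#' `p1` when `D < 0`.
#'
#' @param m a [snp_matrix].
#' @param labels named sample-to-taxon map (defaults to `m$taxon`).
#' @param focal_taxa focal taxon labels.
#' @param outgroup outgroup taxon label.
#' @param alpha significance level on the corrected p-values (default 0.01).
#' @param n_bootstrap bootstrap resamples per test.
#' @param seed integer seed.
#' @param locus_ids optional per-site locus ids (see [pattersons_d()]).
#' @return list with `table` (one row per test: roles, abba, baba, D, Z, p,
#'   Bonferroni-corrected p uncapped and capped, significance), `hybrids`
#'   (flagged sample ids) and `n_tests`.
#' @export
dstat_screen <- function(m, labels = m$taxon, focal_taxa,
                         outgroup, alpha = 0.01, n_bootstrap = 1000,
                         seed = 1L, locus_ids = NULL) {
  specs <- enumerate_triplets(labels, focal_taxa, outgroup,
                              n_bootstrap = n_bootstrap, seed = seed)
  if (!length(specs)) {
    return(list(table = data.frame(), hybrids = character(0), n_tests = 0L))
  }
  cache <- .dstat_cache(m, outgroup)
  # one shared site-resampling plan for the whole screen: each bootstrap
  # replicate resamples the matrix's sites with replacement and every test
  # reuses the replicate through its own retained sites
  bw <- NULL
  if (is.null(locus_ids) && n_bootstrap > 0) {
    S <- ncol(m$codes)
    bw <- with_seed(derive_seeds(seed, 1L),
                    stats::rmultinom(n_bootstrap, S, rep(1 / S, S)))
  }
  res <- lapply(specs, function(sp) pattersons_d(m, sp, locus_ids, cache, bw))
  mtests <- length(res)
  tab <- do.call(rbind, lapply(res, function(r) {
    data.frame(p1 = r$spec$p1, p2 = r$spec$p2, p3 = r$spec$p3,
               outgroup = r$spec$outgroup, n_sites = r$n_sites,
               abba = r$abba, baba = r$baba, D = r$D, Z = r$Z, p = r$p,
               undefined = r$undefined, stringsAsFactors = FALSE)
  }))
  tab$p_bonferroni <- tab$p * mtests
  tab$p_bonferroni_capped <- pmin(1, tab$p_bonferroni)
  tab$significant <- (!tab$undefined & tab$p_bonferroni_capped < alpha) |
    (!tab$undefined & alpha >= 1)
  flagged <- character(0)
  for (r in which(tab$significant)) {
    cand <- if (!is.na(tab$D[r]) && tab$D[r] < 0) tab$p1[r] else tab$p2[r]
    flagged <- c(flagged, cand)
  }
  list(table = tab, hybrids = sort(unique(flagged)), n_tests = mtests)
}

#' Write a D-statistic screen to disk
#' @param screen result of [dstat_screen()].
#' @param table_path tidy CSV path for the per-triplet table.
#' @param hybrids_path plain-text path for the flagged sample ids.
#' @export
write_dstat_csv <- function(screen, table_path = NULL, hybrids_path = NULL) {
  if (!is.null(table_path)) {
    utils::write.csv(screen$table, table_path, row.names = FALSE)
  }
  if (!is.null(hybrids_path)) writeLines(screen$hybrids, hybrids_path)
  invisible(screen)
}
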