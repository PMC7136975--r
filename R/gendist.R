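#' Validate a long-format genotype table
#'
#' @param g data frame with columns `individual_id`, `population_id`,
#'   `locus`, `allele1`, `allele2`; missing alleles are `NA`.
#' @return `g`, with both alleles set `NA` when either is missing.
#' @keywords internal
check_genotypes <- function(g) {
  need <- c("individual_id", "population_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(g))) {
    stop("genotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g$population_id <- as.character(g$population_id)
  g$locus <- as.character(g$locus)
  miss <- is.na(g$allele1) | is.na(g$allele2)
  g$allele1[miss] <- NA
  g$allele2[miss] <- NA
  g
}

#' Read a long-format microsatellite genotype CSV
#'
#' Columns: `individual_id`, `population_id`, `locus`, `allele1`,
#' `allele2`; empty fields are treated as missing alleles.
#' @param path CSV path.
#' @return genotype data frame.
#' @export
read_genotypes <- function(path) {
  check_genotypes(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Allele-size vectors per population for one locus: list(popA = sizes, ...)
.locus_sizes <- function(g_locus, pops) {
  lapply(pops, function(p) {
    gp <- g_locus[g_locus$population_id == p, ]
    sz <- c(gp$allele1, gp$allele2)
    sz[!is.na(sz)]
  })
}

# One-way ANOVA variance components on allele sizes for two populations.
# Among-population component uses the expected-mean-squares coefficient
# n0 = (N - sum(n_i^2) / N) / (a - 1) for unequal sample sizes.
.rst_components <- function(sizes_a, sizes_b) {
  n1 <- length(sizes_a); n2 <- length(sizes_b); N <- n1 + n2
  if (n1 < 1L || n2 < 1L) return(NULL)
  gm <- (sum(sizes_a) + sum(sizes_b)) / N
  ssa <- n1 * (mean(sizes_a) - gm)^2 + n2 * (mean(sizes_b) - gm)^2
  ssw <- sum((sizes_a - mean(sizes_a))^2) + sum((sizes_b - mean(sizes_b))^2)
  if (N - 2L < 1L) return(NULL)
  msa <- ssa / 1            # a - 1 = 1 for two populations
  msw <- ssw / (N - 2L)
  n0 <- (N - (n1^2 + n2^2) / N)  # / (a - 1) = 1
  sigma_a <- (msa - msw) / n0
  c(sigma_a = sigma_a, sigma_w = msw)
}

#' Pairwise R_ST distance matrix
#'
#' For each population pair, allele sizes at each locus enter a one-way
#' analysis of variance with population as the factor; the
#' among-population component `sigma_a^2` (expected-mean-squares estimator
#' with the unequal-sample-size correction) and within-population
#' component `sigma_w^2` are summed over loci before forming
#' `R_ST = sum(sigma_a^2) / sum(sigma_a^2 + sigma_w^2)`. R_ST weights
#' allele-size differences and so reflects a stepwise mutation model of
#' microsatellite evolution. Negative per-locus among-population
#' components are floored at zero by default (keeps distances
#' non-negative for downstream transformation); the final ratio is
#' clamped to [0, 1].
#'
#' @param g genotype data frame (see [read_genotypes()]).
#' @param floor_negative floor negative per-locus among-population
#'   components at zero before summation.
#' @return square symmetric matrix over populations with zero diagonal and
#'   attribute `metric = "RST"`; pairs with no co-typed locus are `NA`
#'   with a warning.
#' @export
rst_matrix <- function(g, floor_negative = TRUE) {
  g <- check_genotypes(g)
  pops <- unique(g$population_id)
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  loci <- unique(g$locus)
  sizes <- lapply(loci, function(l) .locus_sizes(g[g$locus == l, ], pops))
  np <- length(pops)
  out <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    sa <- 0; stot <- 0; any_locus <- FALSE
    for (l in seq_along(loci)) {
      comp <- .rst_components(sizes[[l]][[i]], sizes[[l]][[j]])
      if (is.null(comp)) next
      any_locus <- TRUE
      a <- comp[["sigma_a"]]
      if (floor_negative) a <- max(a, 0)
      sa <- sa + a
      stot <- stot + a + comp[["sigma_w"]]
    }
    if (!any_locus) {
      warning(sprintf("no co-typed locus for pair (%s, %s); R_ST set NA",
                      pops[i], pops[j]))
      out[i, j] <- out[j, i] <- NA_real_
    } else {
      r <- if (stot > 0) sa / stot else 0
      out[i, j] <- out[j, i] <- min(max(r, 0), 1)
    }
  }
  attr(out, "metric") <- "RST"
  out
}

#' Pairwise D_PS (one minus proportion of shared alleles)
#'
#' Per pair and locus, `PS = sum_a min(p_a, q_a)` over the allele
#' frequency distributions `p`, `q` of the two populations;
#' `D_PS = 1 - mean(PS)` over co-typed loci. D_PS tracks allele identity,
#' not size, and so reflects an infinite-allele view of mutation.
#'
#' @param g genotype data frame (see [read_genotypes()]).
#' @return square symmetric matrix over populations, entries in [0, 1],
#'   zero diagonal, attribute `metric = "DPS"`.
#' @export
dps_matrix <- function(g) {
  g <- check_genotypes(g)
  pops <- unique(g$population_id)
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  loci <- unique(g$locus)
  freqs <- lapply(loci, function(l) {
    sz <- .locus_sizes(g[g$locus == l, ], pops)
    lapply(sz, function(s) if (length(s)) table(s) / length(s) else NULL)
  })
  np <- length(pops)
  out <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    ps <- numeric(0)
    for (l in seq_along(loci)) {
      p <- freqs[[l]][[i]]; q <- freqs[[l]][[j]]
      if (is.null(p) || is.null(q)) next
      al <- union(names(p), names(q))
      pv <- stats::setNames(rep(0, length(al)), al); pv[names(p)] <- p
      qv <- stats::setNames(rep(0, length(al)), al); qv[names(q)] <- q
      ps <- c(ps, sum(pmin(pv, qv)))
    }
    if (!length(ps)) {
      warning(sprintf("no co-typed locus for pair (%s, %s); D_PS set NA",
                      pops[i], pops[j]))
      out[i, j] <- out[j, i] <- NA_real_
    } else {
      out[i, j] <- out[j, i] <- 1 - mean(ps)
    }
  }
  attr(out, "metric") <- "DPS"
  out
}
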