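#' Configuration for the synthetic trait-table generator
#'
#' Encodes the structure of the study's phenotype data: 17 genotypes
#' (7 previously parasitised, 10 not) measured monthly July-October with 10
#' replicates for four agronomic traits, plus single-campaign leaf-morphology
#' (October) and chlorophyll-fluorescence (September) trait blocks.
#'
#' Agronomic traits follow configured monthly mean trajectories
#' (non-decreasing, as growth traits must be) with a multiplicative
#' genotype effect and replicate noise, both on the CV scale. Monthly means
#' default to trajectories back-calculated from the published monthly
#' relative growth rates anchored at the October means (height 27.6 cm,
#' branch number 3.22, node number 16.6, stem base diameter 6.5 mm).
#' Leaf and fluorescence blocks are drawn from a latent multivariate
#' Gaussian with a target correlation matrix, split into between-genotype
#' and within-genotype (replicate) components that share the same
#' correlation structure, then located at the published means/SDs; the
#' observation-level correlation therefore converges to the target at
#' large n. Group effects are additive offsets on trait means for the named
#' group (optionally restricted to months).
#'
#' @param genotypes Data frame with columns `id`, `group` (`P`/`NP`).
#' @param months Ordered character vector of month labels.
#' @param replicates Replicates per genotype and month.
#' @param agronomic Named list per trait: `list(means =, cv_genotype =,
#'   cv_resid =)`, `means` one value per month.
#' @param group_effects List of `list(trait =, group =, months = NULL,
#'   offset =)` additive offsets.
#' @param leaf,fluor Multivariate blocks: `list(month =, means =, sds =,
#'   corr =, resid_frac =)` with named `means`/`sds` and a correlation
#'   matrix over the same traits; `resid_frac` is the fraction of total
#'   variance assigned to replicate noise.
#' @param seed Integer seed.
#' @return A validated list of class `trait_gen_config`.
#' @seealso [generate_trait_tables()]
#' @export
trait_gen_config <- function(genotypes = evaluation_panel(),
                             months = c("July", "August", "September",
                                        "October"),
                             replicates = 10L,
                             agronomic = default_agronomic_spec(),
                             group_effects = list(
                               list(trait = "NN", group = "P",
                                    months = c("September", "October"),
                                    offset = 3.3),
                               list(trait = "Fv/Fm", group = "P",
                                    offset = 0.0108),
                               list(trait = "Y(II)", group = "P",
                                    offset = 0.0308),
                               list(trait = "qP", group = "P",
                                    offset = 0.0296)),
                             leaf = default_leaf_spec(),
                             fluor = default_fluor_spec(),
                             seed = 1L) {
  stopifnot(is.data.frame(genotypes),
            all(c("id", "group") %in% names(genotypes)),
            all(genotypes$group %in% c("P", "NP")),
            !anyDuplicated(genotypes$id),
            replicates >= 1)
  for (tr in names(agronomic)) {
    sp <- agronomic[[tr]]
    if (length(sp$means) != length(months))
      stop("agronomic trait ", tr, ": need one mean per month")
    if (any(sp$means <= 0))
      stop("agronomic trait ", tr, ": monthly means must be positive")
    if (is.unsorted(sp$means))
      stop("agronomic trait ", tr,
           ": monthly mean trajectory must be non-decreasing")
  }
  for (blk in list(leaf, fluor)) {
    if (!is.null(blk)) {
      validate_corr_target(blk$corr)
      stopifnot(identical(names(blk$means), rownames(blk$corr)),
                identical(names(blk$means), names(blk$sds)),
                blk$resid_frac >= 0, blk$resid_frac <= 1,
                blk$month %in% months)
    }
  }
  for (ge in group_effects)
    stopifnot(ge$group %in% c("P", "NP"),
              is.null(ge$months) || all(ge$months %in% months))
  structure(list(genotypes = genotypes, months = months,
                 replicates = as.integer(replicates),
                 agronomic = agronomic, group_effects = group_effects,
                 leaf = leaf, fluor = fluor, seed = as.integer(seed)),
            class = "trait_gen_config")
}

#' @rdname trait_gen_config
#' @export
default_agronomic_spec <- function() {
  list(
    H   = list(means = c(10.3, 18.3, 26.6, 27.6),
               cv_genotype = 0.17, cv_resid = 0.08),
    BN  = list(means = c(0.49, 1.75, 2.98, 3.22),
               cv_genotype = 0.40, cv_resid = 0.18),
    NN  = list(means = c(7.5, 12.5, 16.1, 16.6),
               cv_genotype = 0.15, cv_resid = 0.07),
    SBD = list(means = c(4.2, 5.1, 6.2, 6.5),
               cv_genotype = 0.12, cv_resid = 0.06))
}

#' @rdname trait_gen_config
#' @export
default_leaf_spec <- function() {
  traits <- c("LL", "MLW", "LA", "SC")
  corr <- diag(4)
  dimnames(corr) <- list(traits, traits)
  corr["LL", "MLW"] <- corr["MLW", "LL"] <- 0.30
  corr["LL", "LA"]  <- corr["LA", "LL"]  <- 0.88
  corr["MLW", "LA"] <- corr["LA", "MLW"] <- 0.66
  list(month = "October",
       means = c(LL = 4.54, MLW = 0.61, LA = 1.97, SC = 0.68),
       sds   = c(LL = 0.906, MLW = 0.067, LA = 0.374, SC = 0.027),
       corr = corr, resid_frac = 0.3)
}

#' @rdname trait_gen_config
#' @export
default_fluor_spec <- function() {
  traits <- c("Fm", "Fv/Fm", "Y(II)", "Y(NPQ)", "qP")
  corr <- matrix(c(
     1.00,  0.20,  0.20, -0.10,  0.20,
     0.20,  1.00,  0.79, -0.40,  0.60,
     0.20,  0.79,  1.00, -0.50,  0.91,
    -0.10, -0.40, -0.50,  1.00, -0.45,
     0.20,  0.60,  0.91, -0.45,  1.00), 5, 5,
    dimnames = list(traits, traits))
  ## means are the non-parasitised-group baselines; the parasitised group's
  ## advantage enters through the default group_effects offsets
  list(month = "September",
       means = c("Fm" = 0.1401, "Fv/Fm" = 0.6251, "Y(II)" = 0.4501,
                 "Y(NPQ)" = 0.3152, "qP" = 0.7227),
       sds   = c("Fm" = 0.017, "Fv/Fm" = 0.030, "Y(II)" = 0.045,
                 "Y(NPQ)" = 0.030, "qP" = 0.045),
       corr = corr, resid_frac = 0.3)
}

validate_corr_target <- function(corr) {
  if (!isSymmetric(unname(corr)))
    stop("correlation target must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-12))
    stop("correlation target must have a unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(paste0("correlation target is not positive semi-definite ",
                        "(smallest eigenvalue %.4g)"), min(ev)))
  invisible(ev)
}

group_offset <- function(cfg, trait, group, month) {
  off <- 0
  for (ge in cfg$group_effects) {
    if (ge$trait == trait && ge$group == group &&
        (is.null(ge$months) || month %in% ge$months))
      off <- off + ge$offset
  }
  off
}

#' Generate a synthetic long-format trait table
#'
#' Draws one observation per genotype x month x replicate x trait cell
#' according to a [trait_gen_config()]. Traits constrained to `[0, 1]`
#' (shape coefficient and the fluorescence ratios) are clamped to that
#' interval; all other traits are clamped at zero.
#'
#' @param cfg A [trait_gen_config].
#' @return A data frame with columns `genotype`, `group`, `month` (ordered
#'   factor), `replicate`, `trait`, `value`; the seed is attached as
#'   attribute `"seed"`.
#' @examples
#' tt <- generate_trait_tables(trait_gen_config(seed = 3))
#' head(tt)
#' @export
generate_trait_tables <- function(cfg) {
  stopifnot(inherits(cfg, "trait_gen_config"))
  withr::with_seed(cfg$seed, {
    gt <- cfg$genotypes
    n_g <- nrow(gt)
    rep_id <- seq_len(cfg$replicates)
    out <- list()

    ## agronomic block: multiplicative genotype effect, monthly trajectory
    for (tr in names(cfg$agronomic)) {
      sp <- cfg$agronomic[[tr]]
      sdlog <- sqrt(log1p(sp$cv_genotype^2))
      gfac <- exp(stats::rnorm(n_g, 0, sdlog) - sdlog^2 / 2)
      for (mi in seq_along(cfg$months)) {
        month <- cfg$months[mi]
        for (gi in seq_len(n_g)) {
          mu <- sp$means[mi] * gfac[gi] +
            group_offset(cfg, tr, gt$group[gi], month)
          eps <- stats::rnorm(cfg$replicates, 0, sp$cv_resid)
          vals <- pmax(0, mu * (1 + eps))
          out[[length(out) + 1L]] <- data.frame(
            genotype = gt$id[gi], group = gt$group[gi], month = month,
            replicate = rep_id, trait = tr, value = vals,
            stringsAsFactors = FALSE)
        }
      }
    }

    ## correlated multivariate blocks (leaf morphology, fluorescence)
    for (blk in list(cfg$leaf, cfg$fluor)) {
      if (is.null(blk)) next
      traits <- names(blk$means)
      sigma <- diag(blk$sds) %*% blk$corr %*% diag(blk$sds)
      sig_b <- (1 - blk$resid_frac) * sigma
      sig_w <- blk$resid_frac * sigma
      gmeans <- MASS::mvrnorm(n_g, mu = blk$means, Sigma = sig_b)
      gmeans <- matrix(gmeans, nrow = n_g,
                       dimnames = list(NULL, traits))
      for (gi in seq_len(n_g)) {
        mu_g <- gmeans[gi, ] + vapply(
          traits, function(tr) group_offset(cfg, tr, gt$group[gi], blk$month),
          numeric(1))
        obs <- MASS::mvrnorm(cfg$replicates, mu = mu_g, Sigma = sig_w)
        obs <- matrix(obs, nrow = cfg$replicates,
                      dimnames = list(NULL, traits))
        for (tr in traits) {
          vals <- if (tr %in% unit_interval_traits())
            pmin(1, pmax(0, obs[, tr])) else pmax(0, obs[, tr])
          out[[length(out) + 1L]] <- data.frame(
            genotype = gt$id[gi], group = gt$group[gi], month = blk$month,
            replicate = rep_id, trait = tr, value = vals,
            stringsAsFactors = FALSE)
        }
      }
    }

    tt <- do.call(rbind, out)
    tt$month <- factor(tt$month, levels = cfg$months, ordered = TRUE)
    rownames(tt) <- NULL
    attr(tt, "seed") <- cfg$seed
    tt
  })
}

unit_interval_traits <- function()
  c("SC", "Fv/Fm", "Y(II)", "Y(NPQ)", "qP")

#' Read / write a long-format trait table
#'
#' Tab-separated text with header `genotype group month replicate trait
#' value`; the generator seed (when known) is recorded as a `# seed:`
#' comment line.
#'
#' @param tt Trait table data frame.
#' @param path File path.
#' @param months Month ordering used when reading (default: order of first
#'   appearance).
#' @return [read_trait_table()] returns the trait table;
#'   [write_trait_table()] returns `path` invisibly.
#' @export
write_trait_table <- function(tt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(tt, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(tt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path, months = NULL) {
  tt <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("genotype", "group", "month", "replicate", "trait", "value")
  if (!all(need %in% names(tt)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  if (is.null(months)) months <- unique(tt$month)
  tt$month <- factor(tt$month, levels = months, ordered = TRUE)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# seed:"))
    attr(tt, "seed") <- as.integer(sub("# seed:\\s*", "", first))
  tt
}
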