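#' Configuration for the synthetic orchard generator
#'
#' Encodes the study design the generator emulates: four randomized blocks by
#' seven fertilization treatments (waste doses 0, 9, 18, 27, 36 Mg dry matter
#' ha^-1, one fresh-waste dose of 18 Mg dry-matter equivalent, and the
#' standard mineral recommendation) followed over five years. Yields follow a
#' dose response that plateaus at 9 Mg ha^-1 near a 60 Mg ha^-1 maximum, with
#' Gaussian noise; specimens at or above the yield cutoff (the median by
#' default) form the latent high class. Foliar ilr vectors are
#' logistic-normal: multivariate normal around the class centroid in balance
#' space, the low class shifted by \code{delta} on designated balances.
#'
#' @param seed integer seed (drives everything downstream).
#' @param n_blocks number of blocks (default 4).
#' @param years number of cropping years (default 5).
#' @param treatments data.frame with columns \code{treatment}, \code{source}
#'   (\code{dry_waste}/\code{fresh_waste}/\code{mineral}), \code{dose}
#'   (Mg dry-matter-equivalent ha^-1); defaults to the seven-treatment design.
#' @param foliar_centroid named concentrations (g kg^-1, Fv included) of the
#'   high-yield class.
#' @param delta named numeric vector of low-class shifts on specific balances
#'   (names matching basis labels); default places the shift on the
#'   \code{[P | N]} and \code{[S | N,P,K,Mg]} balances.
#' @param ilr_sd per-balance standard deviation of the logistic-normal noise
#'   (scalar or one value per balance).
#' @param ilr_cov optional full covariance matrix (symmetric positive
#'   definite) overriding \code{ilr_sd}.
#' @param yield_base,yield_max control yield at dose 0 and at/after the
#'   plateau dose; \code{yield_plateau} is the dose where response levels
#'   off; \code{yield_sd} the noise standard deviation (Mg ha^-1).
#' @param cutoff yield cutoff; \code{NULL} = median of the realized yields.
#' @param fruit_centroid fruit composition centroid (g kg^-1, Fv included).
#' @param fruit_sd fruit ilr noise standard deviation.
#' @param sbp balance design used by the generator.
#' @return List of class \code{"orchard_config"}.
#' @export
orchard_config <- function(seed = 1, n_blocks = 4, years = 5,
                           treatments = default_treatments(),
                           foliar_centroid = c(N = 20, P = 1.7, K = 15, Ca = 9,
                                               Mg = 3.5, S = 2.8, B = 0.025,
                                               Fv = 947.975),
                           delta = c("[P | N]" = -0.375,
                                     "[S | N,P,K,Mg]" = -0.375),
                           ilr_sd = 0.15, ilr_cov = NULL,
                           yield_base = 42, yield_max = 60,
                           yield_plateau = 9, yield_sd = 8,
                           cutoff = NULL,
                           fruit_centroid = c(N = 12, P = 1.3, K = 14, Ca = 1,
                                              Mg = 1, S = 1.1, B = 0.012,
                                              Fv = 969.588),
                           fruit_sd = 0.10,
                           sbp = sbp_guava()) {
  basis <- as_basis(sbp)
  R <- nrow(basis$psi)
  if (is.null(ilr_cov)) ilr_cov <- diag(rep(ilr_sd, length.out = R)^2, R)
  ev <- eigen(ilr_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("'ilr_cov' must be symmetric positive definite")
  if (!all(names(delta) %in% basis$labels))
    stop("delta names must match basis balance labels")
  if (any(treatments$dose < 0)) stop("doses must be >= 0")
  structure(list(seed = seed, n_blocks = n_blocks, years = years,
                 treatments = treatments, foliar_centroid = foliar_centroid,
                 delta = delta, ilr_cov = ilr_cov,
                 yield_base = yield_base, yield_max = yield_max,
                 yield_plateau = yield_plateau, yield_sd = yield_sd,
                 cutoff = cutoff, fruit_centroid = fruit_centroid,
                 fruit_sd = fruit_sd, basis = basis),
            class = "orchard_config")
}

#' @rdname orchard_config
#' @export
default_treatments <- function() {
  data.frame(treatment = c("D0", "D9", "D18", "D27", "D36", "F18", "RM"),
             source = c(rep("dry_waste", 5), "fresh_waste", "mineral"),
             dose = c(0, 9, 18, 27, 36, 18, 0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic orchard dataset
#'
#' Draws plot-year specimens under the configured design: plateau-response
#' yields with Gaussian noise, latent high/low classes by the yield cutoff,
#' foliar and fruit compositions as logistic-normal draws around class
#' centroids, and yearly amendment batches drawn around the packaged waste
#' analysis means. Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg an \code{"orchard_config"}.
#' @return Object of class \code{"orchard_dataset"}: list with
#'   \code{specimens} (data.frame: id, year, block, treatment, dose, yield,
#'   class, foliar and fruit concentration columns), \code{amendments}
#'   (per year and source), \code{truth} (generator parameters, class
#'   centroids in ilr and concentration units, realized cutoff), and
#'   \code{config}.
#' @export
generate_orchard <- function(cfg) {
  stopifnot(inherits(cfg, "orchard_config"))
  basis <- cfg$basis
  R <- nrow(basis$psi)
  rng <- local_rng(cfg$seed)
  tr <- cfg$treatments[rep(seq_len(nrow(cfg$treatments)), each = cfg$n_blocks), ]
  plots <- data.frame(plot = seq_len(nrow(tr)), tr,
                      block = rep(seq_len(cfg$n_blocks), times = nrow(cfg$treatments)),
                      row.names = NULL)
  spec <- plots[rep(seq_len(nrow(plots)), times = cfg$years), ]
  spec$year <- rep(seq_len(cfg$years), each = nrow(plots))
  spec$id <- sprintf("P%02d_Y%d", spec$plot, spec$year)
  n <- nrow(spec)

  # plateau dose response; mineral treatment taken at plateau level
  eff_dose <- ifelse(spec$source == "mineral", cfg$yield_plateau, spec$dose)
  mu_y <- cfg$yield_base + (cfg$yield_max - cfg$yield_base) *
    pmin(eff_dose, cfg$yield_plateau) / cfg$yield_plateau
  yield <- pmax(mu_y + rng$rnorm(n, sd = cfg$yield_sd), 0.1)
  cutoff <- if (is.null(cfg$cutoff)) stats::median(yield) else cfg$cutoff
  cls <- discretize_yield(yield, cutoff)

  mu_high <- drop(ilr(cfg$foliar_centroid, basis))
  shift <- stats::setNames(numeric(R), basis$labels)
  shift[names(cfg$delta)] <- cfg$delta
  mu_low <- mu_high + shift
  L <- chol(cfg$ilr_cov)
  noise <- matrix(rng$rnorm(n * R), n, R) %*% L
  b_foliar <- noise + rep(1, n) %o% mu_high
  low <- cls == "low"
  b_foliar[low, ] <- noise[low, , drop = FALSE] + rep(1, sum(low)) %o% mu_low
  foliar <- ilr_inv(b_foliar, basis, kappa = 1000)
  colnames(foliar) <- basis$parts

  mu_fruit <- drop(ilr(cfg$fruit_centroid, basis))
  b_fruit <- matrix(rng$rnorm(n * R, sd = cfg$fruit_sd), n, R) +
    rep(1, n) %o% mu_fruit
  fruit <- ilr_inv(b_fruit, basis, kappa = 1000)
  colnames(fruit) <- paste0("fruit_", basis$parts)

  specimens <- data.frame(spec[, c("id", "plot", "block", "treatment", "source",
                                   "dose", "year")],
                          yield = yield, class = cls, foliar, fruit,
                          row.names = NULL, check.names = FALSE)

  wc <- waste_composition()
  amendments <- do.call(rbind, lapply(seq_len(cfg$years), function(y) {
    do.call(rbind, lapply(c("dry", "fresh"), function(src) {
      mean_ <- wc[[paste0(src, "_mean")]]; sd_ <- wc[[paste0(src, "_sd")]]
      data.frame(year = y, source = paste0(src, "_waste"), element = wc$element,
                 unit = wc$unit,
                 content = pmax(mean_ + rng$rnorm(nrow(wc)) * sd_, 0.01 * mean_))
    }))
  }))

  truth <- list(mu_high_ilr = mu_high, mu_low_ilr = mu_low,
                mu_high_conc = drop(ilr_inv(mu_high, basis, 1000)),
                mu_low_conc = drop(ilr_inv(mu_low, basis, 1000)),
                delta = shift, ilr_cov = cfg$ilr_cov, cutoff = cutoff)
  structure(list(specimens = specimens, amendments = amendments,
                 truth = truth, config = cfg),
            class = "orchard_dataset")
}

#' @export
print.orchard_dataset <- function(x, ...) {
  cat(sprintf("Synthetic orchard dataset: %d specimens (%d plots x %d years), cutoff %.2f Mg ha^-1\n",
              nrow(x$specimens), length(unique(x$specimens$plot)),
              x$config$years, x$truth$cutoff))
  cat(sprintf("  classes: %s\n",
              paste(names(table(x$specimens$class)), table(x$specimens$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Run the full pipeline on a synthetic dataset and score recovery
#'
#' Fits the knn diagnosis to the generated foliar compositions, then checks
#' how well the known generating truth is recovered: cross-validated
#' class-recovery accuracy, estimated vs. true class centroids in balance
#' space, and whether the Monte-Carlo TN concentration ranges contain the
#' true high-class centroid.
#'
#' @param ds an \code{"orchard_dataset"}.
#' @param grid,folds,seed,tune passed to \code{\link{cnd}}.
#' @param n_draws Monte-Carlo draws for the TN ranges.
#' @return List with \code{cv_accuracy}, \code{accuracy} (resubstitution),
#'   \code{fit}, \code{centroid_error} (per class, Aitchison norm between
#'   estimated and true centroid), \code{tn_range}, and \code{covers_truth}
#'   (logical: every part's TN range contains the true high-class
#'   concentration).
#' @export
recover_parameters <- function(ds, grid = knn_grid(), folds = 10, seed = 1,
                               tune = TRUE, n_draws = 1e4) {
  stopifnot(inherits(ds, "orchard_dataset"))
  basis <- ds$config$basis
  comp <- as.matrix(ds$specimens[, basis$parts])
  fit <- cnd(comp, ds$specimens$yield, sbp = basis$sbp,
             cutoff = ds$truth$cutoff, grid = grid, folds = folds,
             seed = seed, tune = tune)
  est <- list(high = colMeans(fit$balances[fit$classes == "high", , drop = FALSE]),
              low = colMeans(fit$balances[fit$classes == "low", , drop = FALSE]))
  centroid_error <- c(high = sqrt(sum((est$high - ds$truth$mu_high_ilr)^2)),
                      low = sqrt(sum((est$low - ds$truth$mu_low_ilr)^2)))
  rg <- concentration_ranges(fit, groups = "TN", n_draws = n_draws, seed = seed)
  covers <- if (is.null(rg$TN)) NA else {
    truth <- ds$truth$mu_high_conc[rg$TN$part]
    all(rg$TN$min <= truth & truth <= rg$TN$max)
  }
  list(cv_accuracy = fit$cv_accuracy,
       accuracy = fit$metrics[["accuracy"]],
       fit = fit, centroid_est = est, centroid_error = centroid_error,
       tn_range = rg$TN, covers_truth = covers)
}
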