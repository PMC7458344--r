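#' Configuration for synthetic cohort simulation
#'
#' Bundles and validates the generative parameters for [simulate_cohort()].
#' Defaults describe a plausible resectable pancreatic adenocarcinoma cohort
#' (densities are order-of-magnitude choices, not estimates of any real
#' cohort): ~39 patients, median CD3 density a few hundred cells/mm^2 with
#' roughly log-normal spread, strong CD3-CD8 coupling, weak CD3-CD68
#' coupling, a detection floor below which deconvolution scores drop to
#' zero, a modest panel of infiltration-responsive genes, and survival whose
#' hazard falls with T-cell infiltration.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit for bit.
#' @param cd3_log_mean,cd3_log_sd Mean and sd of latent log CD3 density
#'   (cells/mm^2 on the natural-log scale). CD8 shares the sd with mean
#'   shifted down by log(2) (cytotoxic cells are a subset of T cells); CD68
#'   shares both.
#' @param rho_cd3_cd8 Latent log-scale correlation of CD3 and CD8, in
#'   \[0, 1\].
#' @param rho_cd3_cd68 Latent correlation of CD3 and CD68, in \[-1, 1\]. The
#'   CD8-CD68 correlation is induced as the product of the two (macrophages
#'   couple to cytotoxic cells only through total T-cell infiltration).
#' @param ihc_noise_sd Multiplicative log-normal measurement noise on
#'   observed IHC densities.
#' @param dropout_scale Density (cells/mm^2) below which a deconvolution
#'   score is zeroed with high probability; the dropout probability is
#'   logistic in `log(latent / dropout_scale)`.
#' @param n_genes Total genes in the expression matrix.
#' @param n_signature_genes Number of planted infiltration-responsive genes.
#' @param effect_size Additive log2-expression shift per standardized unit
#'   of latent CD3 infiltration for planted genes.
#' @param baseline_log_mean,baseline_log_sd Baseline log2-TPM distribution.
#' @param hazard_base Baseline event rate (1/month).
#' @param hazard_log_ratio Log hazard ratio per standardized CD3 unit
#'   (negative: infiltration protects).
#' @param censor_rate Rate of the independent exponential censoring clock.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 39L, seed = 1L,
                       cd3_log_mean = log(300), cd3_log_sd = 1,
                       rho_cd3_cd8 = 0.8, rho_cd3_cd68 = 0.2,
                       ihc_noise_sd = 0.2, dropout_scale = 20,
                       n_genes = 1000L, n_signature_genes = 40L,
                       effect_size = 2, baseline_log_mean = 3,
                       baseline_log_sd = 1, hazard_base = 0.02,
                       hazard_log_ratio = -0.5, censor_rate = 0.01) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              cd3_log_mean = cd3_log_mean, cd3_log_sd = cd3_log_sd,
              rho_cd3_cd8 = rho_cd3_cd8, rho_cd3_cd68 = rho_cd3_cd68,
              ihc_noise_sd = ihc_noise_sd, dropout_scale = dropout_scale,
              n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              effect_size = effect_size,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              hazard_base = hazard_base,
              hazard_log_ratio = hazard_log_ratio,
              censor_rate = censor_rate)
  if (cfg$n_patients < 2L) stop("n_patients must be >= 2")
  for (f in c("cd3_log_sd", "ihc_noise_sd", "dropout_scale", "baseline_log_sd",
              "hazard_base", "censor_rate")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) stop(f, " must be strictly positive")
  }
  if (cfg$rho_cd3_cd8 < 0 || cfg$rho_cd3_cd8 > 1) stop("rho_cd3_cd8 must lie in [0, 1]")
  if (abs(cfg$rho_cd3_cd68) > 1) stop("rho_cd3_cd68 must lie in [-1, 1]")
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  if (cfg$n_signature_genes >= cfg$n_genes) stop("n_signature_genes must be < n_genes")
  # CD8-CD68 entry is the product, so the implied 3x3 correlation matrix is
  # positive semi-definite whenever the two inputs are in bounds; verify anyway
  R <- latent_correlation(cfg)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("implied correlation matrix not positive semi-definite ",
         "(offending pair: cd3-cd8 = ", cfg$rho_cd3_cd8,
         ", cd3-cd68 = ", cfg$rho_cd3_cd68, ")")
  }
  structure(cfg, class = "sim_config")
}

latent_correlation <- function(cfg) {
  r12 <- cfg$rho_cd3_cd8
  r13 <- cfg$rho_cd3_cd68
  matrix(c(1, r12, r13,
           r12, 1, r12 * r13,
           r13, r12 * r13, 1), 3L, 3L,
         dimnames = list(c("cd3", "cd8", "cd68"), c("cd3", "cd8", "cd68")))
}

# multivariate normal draw tolerating semi-definite covariance (rho = 1 is a
# legal degenerate configuration)
rmvnorm_psd <- function(n, mean, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma))
  z <- matrix(stats::rnorm(n * nrow(sigma)), n, nrow(sigma))
  sweep(z %*% t(L), 2L, mean, `+`)
}

#' Simulate a synthetic IHC + RNA-seq cohort
#'
#' Generates a cohort with the statistical structure the concordance
#' analysis assumes, so the whole pipeline is testable without patient data:
#'
#' * Latent per-patient (CD3, CD8, CD68) densities from a correlated
#'   multivariate normal on the log scale, exponentiated.
#' * Observed IHC densities = latent density times log-normal measurement
#'   noise.
#' * Deconvolution scores per emulated method: each marker's latent density
#'   is partitioned across that marker's constituent cell types by a fixed
#'   Dirichlet draw per cohort (so the sum rule recovers the latent
#'   composite exactly before dropout); non-constituent catalog cell types
#'   get independent log-normal scores. Every score is then zeroed with
#'   probability logistic in `log(dropout_scale / score)`, reproducing the
#'   zero-inflation that deconvolution shows in poorly infiltrated tumors.
#' * Expression: baseline log2-TPM is i.i.d. normal; planted signature
#'   genes gain `effect_size` log2 units per standardized unit of latent
#'   CD3. TPM is `2^log2expr - 1`, floored at zero.
#' * Survival: exponential with hazard
#'   `hazard_base * exp(hazard_log_ratio * z_cd3)`, censored by an
#'   independent exponential clock.
#'
#' @param config A [sim_config()].
#' @param methods Deconvolution methods to emulate (any subset of
#'   `"cibersort_lm22"`, `"xcell64"`).
#' @return A `synthetic_cohort`: list with `ihc` (an `ihc_table`),
#'   `expression` ([expression_matrix()], TPM), `decon` (named list of
#'   [deconvolution_result()]), `truth` (list: `latent` data frame with
#'   per-patient latent densities and standardized CD3, `planted_genes`)
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            methods = c("cibersort_lm22", "xcell64")) {
  stopifnot(inherits(config, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  withr_seed(config$seed, {
    n <- config$n_patients
    patients <- sprintf("P%03d", seq_len(n))

    mu <- c(cd3 = config$cd3_log_mean,
            cd8 = config$cd3_log_mean - log(2),
            cd68 = config$cd3_log_mean)
    R <- latent_correlation(config)
    sigma <- config$cd3_log_sd^2 * R
    log_latent <- rmvnorm_psd(n, mu, sigma)
    colnames(log_latent) <- colnames(R)
    latent <- exp(log_latent)
    z_cd3 <- as.vector(scale(log_latent[, "cd3"]))

    noise <- function() exp(stats::rnorm(n, 0, config$ihc_noise_sd))
    ihc <- data.frame(patient = patients,
                      cd3 = latent[, "cd3"] * noise(),
                      cd8 = latent[, "cd8"] * noise(),
                      cd68 = latent[, "cd68"] * noise(),
                      stringsAsFactors = FALSE)

    decon <- lapply(methods, function(m) {
      simulate_decon(m, latent, patients, config)
    })
    names(decon) <- methods

    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    planted <- sort(sample(genes, config$n_signature_genes))
    log2e <- matrix(stats::rnorm(config$n_genes * n, config$baseline_log_mean,
                                 config$baseline_log_sd),
                    config$n_genes, n, dimnames = list(genes, patients))
    log2e[planted, ] <- log2e[planted, ] +
      config$effect_size * matrix(z_cd3, length(planted), n, byrow = TRUE)
    tpm <- pmax(2^log2e - 1, 0)

    rate <- config$hazard_base * exp(config$hazard_log_ratio * z_cd3)
    t_event <- stats::rexp(n, rate)
    t_censor <- stats::rexp(n, config$censor_rate)
    ihc$time <- pmin(t_event, t_censor)
    ihc$event <- t_event <= t_censor
    ihc$pathology <- "PDA"
    class(ihc) <- c("ihc_table", "data.frame")

    structure(list(
      ihc = ihc,
      expression = expression_matrix(tpm, transform = "tpm"),
      decon = decon,
      truth = list(latent = data.frame(patient = patients,
                                       cd3 = latent[, "cd3"],
                                       cd8 = latent[, "cd8"],
                                       cd68 = latent[, "cd68"],
                                       z_cd3 = z_cd3,
                                       stringsAsFactors = FALSE),
                   planted_genes = planted),
      config = config), class = "synthetic_cohort")
  })
}

# one emulated deconvolution table: markers partitioned by a fixed Dirichlet
# draw, bystander cell types as independent log-normal noise, then dropout
simulate_decon <- function(method, latent, patients, config) {
  mapping <- default_mapping(method)
  catalog <- mapping$catalog
  n <- nrow(latent)
  scores <- matrix(0, length(catalog), n, dimnames = list(catalog, patients))

  # T-cell subtypes partition latent CD3; macrophage subtypes partition CD68.
  # CD8 constituents are a subset of the CD3 partition, mirroring the real
  # mapping where the CD8 composite nests inside CD3.
  partition <- function(marker, latent_col) {
    cons <- mapping$markers[[marker]]
    w <- stats::rgamma(length(cons), 1)   # Dirichlet(1,...,1), fixed per cohort
    w <- w / sum(w)
    scores[cons, ] <<- outer(w, latent[, latent_col])
  }
  partition("CD3", "cd3")
  partition("CD68", "cd68")

  bystanders <- setdiff(catalog, unlist(mapping$markers))
  if (length(bystanders) > 0L) {
    scores[bystanders, ] <- matrix(
      stats::rlnorm(length(bystanders) * n,
                    meanlog = config$cd3_log_mean - log(20),
                    sdlog = config$cd3_log_sd),
      length(bystanders), n)
  }

  p_drop <- 1 / (1 + scores / config$dropout_scale)
  keep <- matrix(stats::runif(length(scores)) >= p_drop,
                 nrow(scores), ncol(scores))
  deconvolution_result(scores * keep, method = method, semantics = "arbitrary")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d genes (%d planted), methods: %s\n",
              nrow(x$ihc), nrow(x$expression),
              length(x$truth$planted_genes),
              paste(names(x$decon), collapse = ", ")))
  cat(sprintf("  events: %d/%d; median observed CD3 = %.0f cells/mm^2\n",
              sum(x$ihc$event), nrow(x$ihc), stats::median(x$ihc$cd3)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same on-disk formats the readers consume: expression TSV, IHC
#' CSV, one deconvolution TSV per method, a truth TSV of latent densities,
#' and a sidecar text file listing the planted genes.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_ihc(cohort$ihc, file.path(dir, "ihc.csv"))
  for (m in names(cohort$decon)) {
    write_deconvolution(cohort$decon[[m]], file.path(dir, paste0("decon_", m, ".tsv")))
  }
  utils::write.table(cohort$truth$latent, file.path(dir, "truth_latent.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(cohort$truth$planted_genes, file.path(dir, "truth_planted_genes.txt"))
  invisible(dir)
}
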