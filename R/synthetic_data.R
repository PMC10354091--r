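#' Simulation configuration for a competitive chemoproteomic experiment
#'
#' The generator emulates the canonical competition layout: per run, two
#' shared no-probe negative controls (compound at 10 and 50 uM), and per
#' probe one probe-only sample, two active-competition samples (parent
#' compound and active analog pretreatment) and one inactive-competition
#' (inactive analog) sample. Planted proteins fall in three classes:
#' specific targets (enriched by the probe, competed by active
#' compounds), probe-nonspecific binders (enriched by the probe in every
#' probe-containing sample, regardless of pretreatment) and sticky
#' background proteins (same expectation everywhere).
#'
#' Expected PSM means, for a protein of abundance \eqn{a_i}:
#' background \eqn{a_i d} in every sample; specific targets
#' \eqn{a_i d E} in probe-only and inactive-competition samples,
#' \eqn{a_i d E (1 - c)} under active competition and
#' \eqn{a_i d E \epsilon} in no-probe controls; probe-nonspecific binders
#' \eqn{a_i d E} in every probe-containing sample and
#' \eqn{a_i d E \epsilon} in no-probe controls. Counts are drawn
#' negative-binomial (Poisson in the \code{dispersion = 0} limit) and
#' thinned by dropout.
#'
#' @param n_proteins Proteome size.
#' @param n_runs Independent runs (default 3).
#' @param probes Probe tokens (default two probes).
#' @param n_specific_targets Planted specific targets.
#' @param n_probe_nonspecific Planted probe-nonspecific binders.
#' @param enrichment_factor Probe enrichment multiplier E (> 1).
#' @param competition_completeness Fraction c of probe labeling competed
#'   away by active compounds (in [0, 1]).
#' @param background_binding Fraction \eqn{\epsilon} of enrichment
#'   leaking into no-probe controls (bead background).
#' @param depth Expected PSM per unit-abundance background protein.
#' @param dispersion Negative-binomial overdispersion (variance
#'   \eqn{\mu + dispersion \mu^2}); 0 gives Poisson counts.
#' @param dropout Per-(protein, sample) probability of missing entirely.
#' @param abundance_sdlog Lognormal sd of per-protein abundance
#'   multipliers.
#' @param shared_target_fraction Fraction of specific targets engaged by
#'   every probe; the rest are assigned to single probes in rotation.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_proteins = 2000L, n_runs = 3L,
                       probes = c("AOyne", "PZyne"),
                       n_specific_targets = 20L, n_probe_nonspecific = 30L,
                       enrichment_factor = 10, competition_completeness = 0.9,
                       background_binding = 0.05, depth = 5,
                       dispersion = 0.2, dropout = 0.05,
                       abundance_sdlog = 0.5, shared_target_fraction = 1,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_runs = as.integer(n_runs),
              probes = as.character(probes),
              n_specific_targets = as.integer(n_specific_targets),
              n_probe_nonspecific = as.integer(n_probe_nonspecific),
              enrichment_factor = enrichment_factor,
              competition_completeness = competition_completeness,
              background_binding = background_binding, depth = depth,
              dispersion = dispersion, dropout = dropout,
              abundance_sdlog = abundance_sdlog,
              shared_target_fraction = shared_target_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_proteins < 1 || n_runs < 1 || length(probes) < 1)
      rlang::abort("n_proteins, n_runs and probes must be non-empty",
                   class = "competeMS_config_error")
    if (n_specific_targets + n_probe_nonspecific > n_proteins)
      rlang::abort("planted classes exceed the proteome size",
                   class = "competeMS_config_error")
    if (enrichment_factor < 1)
      rlang::abort("enrichment_factor must be >= 1",
                   class = "competeMS_config_error")
    if (competition_completeness < 0 || competition_completeness > 1 ||
        background_binding < 0 || dropout < 0 || dropout > 1 ||
        shared_target_fraction < 0 || shared_target_fraction > 1)
      rlang::abort("rate parameters out of range",
                   class = "competeMS_config_error")
    if (depth <= 0 || dispersion < 0)
      rlang::abort("depth must be > 0 and dispersion >= 0",
                   class = "competeMS_config_error")
  })
  structure(cfg, class = "sim_config")
}

sim_design <- function(cfg) {
  rows <- list()
  for (r in seq_len(cfg$n_runs)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("R%d_ctrl_cmpd%d", r, c(10L, 50L)),
      run_id = r, probe = "NONE", role = "no_probe_control",
      treatment_label = sprintf("%d uM compound, no probe", c(10L, 50L)),
      concentration_uM = c(10, 50))
    for (p in cfg$probes) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("R%d_%s_%s", r, p,
                            c("probe", "comp_parent", "comp_analog", "inactive")),
        run_id = r, probe = p,
        role = c("probe_only", "active_competition", "active_competition",
                 "inactive_competition"),
        treatment_label = c("10 uM probe",
                            "40 uM parent compound + 10 uM probe",
                            "40 uM active analog + 10 uM probe",
                            "40 uM inactive analog + 10 uM probe"),
        concentration_uM = c(10, 40, 40, 40))
    }
  }
  sample_design(dplyr::bind_rows(rows))
}

#' Generate a full synthetic competition experiment
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with elements \code{design} (a
#'   \code{\link{sample_design}}), \code{tables} (a
#'   \code{\link{run_tables}}) and \code{truth} (tibble with per-protein
#'   \code{class}, \code{abundance} and \code{engaged_probes}).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- sim_design(cfg)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_proteins
    acc <- sprintf("SYN%05d", seq_len(n))
    gene <- sprintf("Gene%05d", seq_len(n))
    cls <- rep("background", n)
    if (cfg$n_specific_targets > 0)
      cls[seq_len(cfg$n_specific_targets)] <- "specific_target"
    if (cfg$n_probe_nonspecific > 0)
      cls[cfg$n_specific_targets + seq_len(cfg$n_probe_nonspecific)] <-
        "probe_nonspecific"
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)

    engaged <- rep(NA_character_, n)
    t_idx <- which(cls == "specific_target")
    if (length(t_idx) > 0) {
      n_shared <- round(cfg$shared_target_fraction * length(t_idx))
      engaged[t_idx] <- paste(cfg$probes, collapse = ";")
      if (n_shared < length(t_idx)) {
        singles <- t_idx[(n_shared + 1):length(t_idx)]
        engaged[singles] <-
          cfg$probes[((seq_along(singles) - 1L) %% length(cfg$probes)) + 1L]
      }
    }

    base_mu <- abundance * cfg$depth
    E <- cfg$enrichment_factor; c_ <- cfg$competition_completeness
    eps <- cfg$background_binding
    engaged_by <- lapply(stats::setNames(cfg$probes, cfg$probes), function(p)
      vapply(strsplit(ifelse(is.na(engaged), "", engaged), ";", fixed = TRUE),
             function(x) p %in% x, logical(1)))

    tables <- stats::setNames(vector("list", nrow(design)), design$sample_id)
    for (si in seq_len(nrow(design))) {
      role <- design$role[si]; probe <- design$probe[si]
      mu <- base_mu
      if (role == "no_probe_control") {
        idx <- cls != "background"
        mu[idx] <- base_mu[idx] * E * eps
      } else {
        ns <- cls == "probe_nonspecific"
        mu[ns] <- base_mu[ns] * E
        tg <- cls == "specific_target" & engaged_by[[probe]]
        fac <- if (role == "active_competition") E * (1 - c_) else E
        mu[tg] <- base_mu[tg] * fac
      }
      psm <- if (cfg$dispersion > 0) {
        stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
      } else {
        stats::rpois(n, lambda = mu)
      }
      if (cfg$dropout > 0) {
        psm[stats::runif(n) < cfg$dropout] <- 0L
      }
      keep <- which(psm > 0)
      psm_k <- psm[keep]
      extra <- stats::rbinom(length(keep), size = psm_k - 1L, prob = 0.6)
      n_pep <- 1L + extra
      n_uni <- stats::rbinom(length(keep), size = n_pep, prob = 0.8)
      tables[[si]] <- tibble::tibble(
        accession = acc[keep], gene_symbol = gene[keep],
        psm_count = as.integer(psm_k), n_peptides = as.integer(n_pep),
        n_unique_peptides = as.integer(n_uni))
    }

    truth <- tibble::tibble(accession = acc, gene_symbol = gene,
                            class = cls, abundance = abundance,
                            engaged_probes = engaged)
    list(design = design, tables = run_tables(design, tables), truth = truth)
  })
}

#' Score candidate recovery against simulation ground truth
#'
#' Precision, recall and F1 are computed against the specific targets
#' engaged by the scored probe. Probe-nonspecific binders are reported
#' separately: their exclusion from the candidate list is the filter
#' doing its job ("competition-removed" true negatives).
#'
#' @param candidate_set A \code{candidate_set}.
#' @param truth Ground-truth tibble from \code{\link{generate_experiment}}.
#' @param probe Probe token; defaults to the candidate set's probe.
#' @return List with \code{precision}, \code{recall}, \code{f1},
#'   \code{tp}, \code{fp}, \code{fn}, \code{n_candidates},
#'   \code{n_targets}, \code{n_nonspecific}, \code{n_nonspecific_removed}.
#' @export
score_recovery <- function(candidate_set, truth,
                           probe = candidate_set$probe) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  pred <- candidate_set$candidates$accession
  unknown <- setdiff(pred, truth$accession)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("accession(s) absent from ground truth: %s",
                         paste(utils::head(unknown, 5), collapse = ", ")),
                 class = "competeMS_scoring_error")
  }
  pos <- truth$accession[truth$class == "specific_target" &
                           !is.na(truth$engaged_probes) &
                           vapply(truth$engaged_probes, function(x)
                             probe %in% strsplit(x, ";", fixed = TRUE)[[1]],
                             logical(1))]
  nonspec <- truth$accession[truth$class == "probe_nonspecific"]
  tp <- length(intersect(pred, pos))
  fp <- length(setdiff(pred, pos))
  fn <- length(setdiff(pos, pred))
  precision <- if (length(pred) > 0) tp / length(pred) else NA_real_
  recall <- if (length(pos) > 0) tp / length(pos) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn,
       n_candidates = length(pred), n_targets = length(pos),
       n_nonspecific = length(nonspec),
       n_nonspecific_removed = length(setdiff(nonspec, pred)))
}

#' Generate a synthetic deconvoluted intact-mass spectrum
#'
#' Plants an unmodified peak at the protein mass and, when
#' \code{modified_fraction > 0}, an adduct peak at the protein mass plus
#' \code{stoichiometry} ligand masses, with intensities split according
#' to the modified fraction; both masses are jittered with Gaussian
#' error. Optional uniform low-intensity noise peaks emulate deconvolution
#' artifacts. \code{modified_fraction = 0} yields a single real peak (the
#' profile of a construct whose reactive residue is mutated away).
#'
#' @param protein_mass Unmodified protein mass in Da.
#' @param ligand A \code{\link{ligand_spec}}.
#' @param modified_fraction Fraction of protein carrying the adduct
#'   (in [0, 1]).
#' @param stoichiometry Planted number of ligand additions.
#' @param mass_error_sd Gaussian mass error (Da) on each real peak.
#' @param n_noise_peaks Number of uniform noise peaks.
#' @param seed Optional integer seed for reproducibility.
#' @param label Spectrum label.
#' @return A \code{\link{deconvoluted_spectrum}}.
#' @export
generate_spectrum <- function(protein_mass, ligand, modified_fraction,
                              stoichiometry = 1L, mass_error_sd = 0,
                              n_noise_peaks = 0L, seed = NULL,
                              label = "synthetic") {
  stopifnot(inherits(ligand, "ligand_spec"),
            modified_fraction >= 0, modified_fraction <= 1,
            protein_mass > 0, stoichiometry >= 1, mass_error_sd >= 0)
  gen <- function() {
    mass <- protein_mass + stats::rnorm(1, 0, mass_error_sd)
    intensity <- 100 * (1 - modified_fraction)
    if (modified_fraction > 0) {
      mass <- c(mass, protein_mass + stoichiometry * ligand$mass +
                  stats::rnorm(1, 0, mass_error_sd))
      intensity <- c(intensity, 100 * modified_fraction)
    }
    if (n_noise_peaks > 0) {
      mass <- c(mass, stats::runif(n_noise_peaks, protein_mass - 3000,
                                   protein_mass + 3000))
      intensity <- c(intensity, stats::runif(n_noise_peaks, 0.5, 5))
    }
    deconvoluted_spectrum(mass, intensity, label = label)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
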