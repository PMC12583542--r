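# Synthetic tumor-microenvironment cohort generator.
#
# The generator plants known niche structure (cluster point processes with
# prototype marker profiles) and proportional-hazards survival linked to
# niche abundances and stage, so that every downstream stage -- phenotyping,
# niche discovery, matching, risk modelling -- can be tested against ground
# truth without access to restricted cohort data. All distributional choices
# are stand-ins for data whose generative model is unknown; see the methods
# vignette for what they do and do not emulate.

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Default planted niche prototypes
#'
#' Four prototype neighborhoods emulating the dominant niche families seen
#' in lung tumor microarrays: carcinoma-dominant, immunosuppressive
#' (PD-L1+) carcinoma, lymphocyte-rich, and macrophage-rich. Each prototype
#' is a 12-marker Bernoulli probability vector plus a tissue compartment
#' and a spatial cluster spread (isotropic Gaussian sigma in micrometers).
#'
#' @return A tibble with one row per prototype: `prototype`, `compartment`,
#'   `sigma_um`, and one probability column per marker.
#' @export
default_prototypes <- function() {
  mk <- marker_panel()
  base <- matrix(0.01, nrow = 4, ncol = 12, dimnames = list(NULL, mk))
  base[1, "CK"] <- 0.95
  base[2, c("CK", "PDL1")] <- c(0.90, 0.85)
  base[3, c("CD3", "CD4", "CD8", "CD20", "FOXP3", "PD1", "GRB")] <-
    c(0.85, 0.50, 0.30, 0.20, 0.10, 0.25, 0.15)
  base[4, c("CD68", "CD163")] <- c(0.90, 0.50)
  dplyr::bind_cols(
    tibble::tibble(
      prototype   = c("carcinoma", "icc", "lymphocyte", "macrophage"),
      compartment = c("carcinoma", "carcinoma", "stroma", "stroma"),
      sigma_um    = c(18, 18, 15, 16)
    ),
    tibble::as_tibble(base)
  )
}

#' Default patient archetypes
#'
#' Mixture weights over the planted prototypes describing three patient
#' phenotypes: immunologically cold, hot (lymphocyte-infiltrated) and
#' immunosuppressed tumors. Rows sum to one.
#'
#' @return A numeric matrix, one row per archetype, one column per
#'   prototype.
#' @export
default_archetypes <- function() {
  m <- rbind(
    cold       = c(0.75, 0.05, 0.10, 0.10),
    hot        = c(0.35, 0.05, 0.45, 0.15),
    suppressed = c(0.35, 0.45, 0.10, 0.10)
  )
  colnames(m) <- default_prototypes()$prototype
  m
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults encode
#' the study conditions emulated throughout the package: two centers, up to
#' four 1.5 mm spots per patient, right-skewed cell counts (Poisson counts
#' with a log-normal patient-level intensity), spatially clustered cells
#' from planted prototypes, and exponential proportional-hazards survival
#' with independent exponential censoring calibrated to a target censored
#' fraction.
#'
#' @param n_patients_per_center_per_subtype Patients per center per subtype.
#' @param subtypes Tumor subtypes to simulate (default LUAD and LUSC).
#' @param spots_per_patient Tissue spots per patient (default 4).
#' @param spot_diameter_mm Spot diameter in millimeters (default 1.5).
#' @param prototypes Planted prototype table, see [default_prototypes()].
#' @param archetypes Patient archetype mixture-weight matrix, rows sum to 1.
#' @param mean_cells_per_spot Expected cells per spot before patient-level
#'   intensity scaling (default 220).
#' @param intensity_sdlog Log-normal sd of the patient-level cell intensity
#'   multiplier (default 0.35); produces the right-skewed, heavy-tailed
#'   per-spot counts the analysis normalizes away.
#' @param hazard_betas Log-hazard coefficients over (prototype abundance
#'   proportions, UICC8 stage). Length must be `nrow(prototypes) + 1`.
#' @param baseline_hazard Baseline event rate per month (default 0.012).
#' @param censoring_rate Target censored fraction in `[0, 1]` (default 0.35).
#' @param stage_probs Sampling probabilities for UICC8 stages 1-4.
#' @param r1_rate,adjuvant_rate Fractions of incomplete resections and
#'   adjuvant-treated patients (exercise the cohort-selection rules).
#' @param seed Integer seed; identical configs reproduce identical cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients_per_center_per_subtype = 2, seed = 1)
#' cohort <- generate_cohort(cfg)
#' dplyr::count(cohort$cells, compartment)
sim_config <- function(n_patients_per_center_per_subtype = 25,
                       subtypes = c("LUAD", "LUSC"),
                       spots_per_patient = 4,
                       spot_diameter_mm = 1.5,
                       prototypes = default_prototypes(),
                       archetypes = default_archetypes(),
                       mean_cells_per_spot = 220,
                       intensity_sdlog = 0.35,
                       hazard_betas = NULL,
                       baseline_hazard = 0.012,
                       censoring_rate = 0.35,
                       stage_probs = c(0.45, 0.30, 0.20, 0.05),
                       r1_rate = 0.05,
                       adjuvant_rate = 0.10,
                       seed = 1L) {
  assert_number(n_patients_per_center_per_subtype, "n_patients_per_center_per_subtype", 0)
  assert_number(spots_per_patient, "spots_per_patient", 1)
  assert_number(spot_diameter_mm, "spot_diameter_mm", .Machine$double.eps)
  assert_number(baseline_hazard, "baseline_hazard", 0)
  assert_number(censoring_rate, "censoring_rate", 0, 1)
  stopifnot(is.data.frame(prototypes), nrow(prototypes) >= 1)
  pm <- as.matrix(prototypes[, marker_panel()])
  if (any(pm < 0 | pm > 1)) stop("marker probabilities must lie in [0, 1]")
  if (any(prototypes$sigma_um <= 0)) stop("prototype sigma_um must be > 0")
  archetypes <- as.matrix(archetypes)
  if (ncol(archetypes) != nrow(prototypes)) {
    stop("archetype columns must match the number of prototypes")
  }
  if (any(archetypes < 0) || any(abs(rowSums(archetypes) - 1) > 1e-8)) {
    stop("archetype mixture weights must be nonnegative and sum to 1")
  }
  if (is.null(hazard_betas)) {
    hazard_betas <- stats::setNames(
      numeric(nrow(prototypes) + 1L),
      c(prototypes$prototype, "stage")
    )
    hazard_betas[intersect(c("lymphocyte", "macrophage", "icc"), names(hazard_betas))] <-
      c(lymphocyte = -0.7, macrophage = 0.3, icc = 0.3)[
        intersect(c("lymphocyte", "macrophage", "icc"), names(hazard_betas))]
    hazard_betas["stage"] <- log(1.4)
  }
  if (length(hazard_betas) != nrow(prototypes) + 1L) {
    stop("hazard_betas must have length nrow(prototypes) + 1 (abundances + stage)")
  }
  stopifnot(length(stage_probs) == 4, all(stage_probs >= 0))
  structure(
    list(
      n_patients_per_center_per_subtype = as.integer(n_patients_per_center_per_subtype),
      subtypes = subtypes,
      spots_per_patient = as.integer(spots_per_patient),
      spot_diameter_mm = spot_diameter_mm,
      prototypes = prototypes,
      archetypes = archetypes,
      mean_cells_per_spot = mean_cells_per_spot,
      intensity_sdlog = intensity_sdlog,
      hazard_betas = hazard_betas,
      baseline_hazard = baseline_hazard,
      censoring_rate = censoring_rate,
      stage_probs = stage_probs / sum(stage_probs),
      r1_rate = r1_rate,
      adjuvant_rate = adjuvant_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate the cells of one tissue spot
#'
#' Places cells by a cluster point process: prototype seed points are drawn
#' uniformly in the spot disk with per-prototype intensity proportional to
#' the archetype mixture weight; each cell picks a prototype by the mixture
#' weights, a seed point of that prototype, and an isotropic Gaussian
#' offset with the prototype's sigma (resampled to stay inside the disk).
#' Marker booleans are independent Bernoulli draws from the prototype's
#' probability vector; the compartment label is copied from the prototype.
#'
#' @param archetype Numeric mixture-weight vector over the prototypes.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_cells Optional fixed cell count; by default drawn Poisson with
#'   the configured spot intensity.
#' @return A tibble with one row per cell: `x_um`, `y_um`, the 12 logical
#'   marker columns, `compartment`, and the planted `prototype` label.
#' @export
generate_spot <- function(archetype, config, seed, n_cells = NULL) {
  if (length(archetype) == 0 || sum(archetype) <= 0) {
    stop("archetype must contain at least one positive mixture weight")
  }
  proto <- config$prototypes
  if (length(archetype) != nrow(proto)) {
    stop("archetype length must match the number of prototypes")
  }
  if (any(proto$sigma_um <= 0)) stop("prototype sigma_um must be > 0")
  w <- archetype / sum(archetype)
  radius <- config$spot_diameter_mm * 1000 / 2
  pm <- as.matrix(proto[, marker_panel()])

  with_seed(seed, {
    n <- n_cells %||% stats::rpois(1, config$mean_cells_per_spot)
    if (n == 0) {
      empty_cell_block()
    } else {
    # seed points: ~1 per 45 cells, split by mixture weight, >=1 where w > 0
    n_seeds_total <- max(3L, as.integer(round(n / 45)))
    n_seeds <- ifelse(w > 0, pmax(1L, stats::rpois(length(w), w * n_seeds_total)), 0L)
    seed_xy <- lapply(seq_along(w), function(p) {
      if (n_seeds[p] == 0) return(NULL)
      runif_disk(n_seeds[p], radius)
    })
    proto_id <- sample.int(length(w), n, replace = TRUE, prob = w)
    sigma <- proto$sigma_um[proto_id]
    pick <- vapply(proto_id, function(p) sample.int(n_seeds[p], 1L), integer(1))
    cx <- vapply(seq_len(n), function(i) seed_xy[[proto_id[i]]][pick[i], 1], numeric(1))
    cy <- vapply(seq_len(n), function(i) seed_xy[[proto_id[i]]][pick[i], 2], numeric(1))
    x <- cx + stats::rnorm(n, 0, sigma)
    y <- cy + stats::rnorm(n, 0, sigma)
    # resample offsets that escape the spot disk (rare); clamp as last resort
    out <- which(x^2 + y^2 > radius^2)
    for (i in out) {
      for (tries in 1:20) {
        x[i] <- cx[i] + stats::rnorm(1, 0, sigma[i])
        y[i] <- cy[i] + stats::rnorm(1, 0, sigma[i])
        if (x[i]^2 + y[i]^2 <= radius^2) break
      }
      r2 <- x[i]^2 + y[i]^2
      if (r2 > radius^2) {
        s <- radius / sqrt(r2) * 0.999
        x[i] <- x[i] * s
        y[i] <- y[i] * s
      }
    }
    marks <- matrix(
      stats::rbinom(n * 12L, 1L, as.vector(t(pm[proto_id, , drop = FALSE]))) == 1L,
      nrow = n, ncol = 12L, byrow = TRUE, dimnames = list(NULL, marker_panel())
    )
    dplyr::bind_cols(
      tibble::tibble(x_um = x, y_um = y),
      tibble::as_tibble(marks),
      tibble::tibble(
        compartment = proto$compartment[proto_id],
        prototype = proto$prototype[proto_id]
      )
    )
    }
  })
}

runif_disk <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

empty_cell_block <- function() {
  mk <- stats::setNames(rep(list(logical(0)), 12), marker_panel())
  dplyr::bind_cols(
    tibble::tibble(x_um = numeric(0), y_um = numeric(0)),
    tibble::as_tibble(mk),
    tibble::tibble(compartment = character(0), prototype = character(0))
  )
}

#' Simulate proportional-hazards survival times
#'
#' Event times are exponential with patient rate
#' `baseline_hazard * exp(beta . z)` where `z` stacks the niche abundance
#' features and the UICC8 stage. Censoring is an independent exponential
#' whose rate `c` is calibrated so that the expected censored fraction
#' equals `censoring_rate`: with patient event rates `lambda_i`, the
#' censored probability is `mean_i c / (c + lambda_i)`, solved for `c` by
#' root finding. `censoring_rate = 0` yields no censoring.
#'
#' @param features Numeric matrix, one row per patient, columns matching
#'   `config$hazard_betas`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with `os_months`, `event` (0/1) and the true
#'   `hazard_rate` per patient.
#' @export
generate_survival <- function(features, config, seed) {
  features <- as.matrix(features)
  beta <- config$hazard_betas
  if (ncol(features) != length(beta)) {
    stop("feature columns must match the length of hazard_betas")
  }
  if (config$baseline_hazard < 0) stop("baseline_hazard must be nonnegative")
  rate <- config$baseline_hazard * exp(drop(features %*% beta))
  n <- nrow(features)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate)
    q <- config$censoring_rate
    if (q <= 0 || n == 0) {
      t_cens <- rep(Inf, n)
    } else {
      # calibrate the censoring rate c: mean_i c/(c + lambda_i) = q
      f <- function(lc) mean(exp(lc) / (exp(lc) + rate)) - q
      lc <- stats::uniroot(f, lower = log(min(rate)) - 20,
                           upper = log(max(rate)) + 20, tol = 1e-10)$root
      t_cens <- stats::rexp(n, exp(lc))
    }
    tibble::tibble(
      os_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      hazard_rate = rate
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Assembles patients across two centers and the configured subtypes,
#' assigns each patient an archetype, simulates every spot with
#' [generate_spot()], derives per-patient true niche-abundance features
#' from the planted labels, and simulates survival with
#' [generate_survival()]. Optionally writes the four tab-delimited tables
#' (`cells.tsv`, `spots.tsv`, `patients.tsv`, `truth.tsv`).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the tables are written
#'   there with [write_cohort()].
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `cells`, `spots`, `patients` and `ground_truth` (per-cell planted
#'   prototype labels ride along in `cells$prototype`; `ground_truth`
#'   carries per-patient archetype, true abundance features and hazard).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_arm <- config$n_patients_per_center_per_subtype
  grid <- tidyr::expand_grid(
    center = c("A", "B"),
    subtype = config$subtypes,
    idx = seq_len(n_arm)
  )
  n_pat <- nrow(grid)
  proto_names <- config$prototypes$prototype

  if (n_pat == 0) {
    cohort <- empty_cohort()
    if (!is.null(out_dir)) write_cohort(cohort, out_dir)
    return(cohort)
  }

  master <- with_seed(config$seed, {
    list(
      archetype = sample.int(nrow(config$archetypes), n_pat, replace = TRUE),
      uicc8 = sample.int(4L, n_pat, replace = TRUE, prob = config$stage_probs),
      r_status = stats::rbinom(n_pat, 1, config$r1_rate),
      adjuvant = stats::rbinom(n_pat, 1, config$adjuvant_rate) == 1,
      intensity = stats::rlnorm(n_pat, meanlog = -config$intensity_sdlog^2 / 2,
                                sdlog = config$intensity_sdlog),
      spot_seeds = matrix(
        sample.int(.Machine$integer.max - 1L, n_pat * config$spots_per_patient),
        nrow = n_pat
      ),
      area_noise = matrix(stats::rnorm(n_pat * config$spots_per_patient, 0, 0.12),
                          nrow = n_pat),
      area_fail = matrix(stats::runif(n_pat * config$spots_per_patient) < 0.04,
                         nrow = n_pat),
      area_fail_val = matrix(stats::runif(n_pat * config$spots_per_patient,
                                          0.2, 0.6), nrow = n_pat),
      surv_seed = sample.int(.Machine$integer.max - 1L, 1)
    )
  })

  patient_id <- sprintf("P%04d", seq_len(n_pat))
  nominal_area <- pi * (config$spot_diameter_mm / 2)^2

  cells_list <- vector("list", n_pat)
  spots_list <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    arch <- config$archetypes[master$archetype[i], ]
    sp <- vector("list", config$spots_per_patient)
    for (s in seq_len(config$spots_per_patient)) {
      cfg_i <- config
      cfg_i$mean_cells_per_spot <- config$mean_cells_per_spot * master$intensity[i]
      blk <- generate_spot(arch, cfg_i, seed = master$spot_seeds[i, s])
      blk$patient_id <- patient_id[i]
      blk$spot_id <- sprintf("%s_S%d", patient_id[i], s)
      sp[[s]] <- blk
    }
    cells_i <- dplyr::bind_rows(sp)
    tumor_frac <- vapply(sp, function(b) {
      if (nrow(b) == 0) return(0.8)
      mean(b$compartment %in% tumor_compartments())
    }, numeric(1))
    aligned <- pmax(0.05, nominal_area * (1 + master$area_noise[i, ]))
    aligned[master$area_fail[i, ]] <- master$area_fail_val[i, master$area_fail[i, ]]
    pid <- patient_id[i]
    spots_list[[i]] <- tibble::tibble(
      patient_id = pid,
      spot_id = sprintf("%s_S%d", pid, seq_len(config$spots_per_patient)),
      aligned_area_mm2 = aligned,
      tumor_area_mm2 = pmin(aligned, aligned * pmax(tumor_frac, 0.05)),
      qc_pass = aligned >= 0.7 & aligned <= 3.0
    )
    cells_list[[i]] <- cells_i
  }
  cells <- dplyr::bind_rows(cells_list)
  cells$cell_id <- sprintf("C%07d", seq_len(nrow(cells)))
  cells <- dplyr::relocate(cells, "cell_id", "patient_id", "spot_id")
  spots <- dplyr::bind_rows(spots_list)

  # per-patient true niche abundance features = planted label proportions
  abund <- matrix(0, n_pat, length(proto_names),
                  dimnames = list(patient_id, proto_names))
  tab <- table(cells$patient_id, factor(cells$prototype, levels = proto_names))
  abund[rownames(tab), ] <- as.matrix(tab) / pmax(rowSums(tab), 1)

  features <- cbind(abund, stage = master$uicc8)
  surv <- generate_survival(features, config, seed = master$surv_seed)
  # spare the selection rules a degenerate zero-survival cohort
  surv$os_months <- pmax(surv$os_months, 0.1)

  patients <- tibble::tibble(
    patient_id = patient_id,
    center = grid$center,
    subtype = grid$subtype,
    uicc8 = as.integer(master$uicc8),
    r_status = as.integer(master$r_status),
    adjuvant = master$adjuvant,
    os_months = surv$os_months,
    event = surv$event
  )
  ground_truth <- tibble::tibble(
    patient_id = patient_id,
    archetype = rownames(config$archetypes)[master$archetype] %||%
      as.character(master$archetype),
    true_hazard = surv$hazard_rate
  )
  ground_truth <- dplyr::bind_cols(ground_truth, tibble::as_tibble(abund))

  cohort <- structure(
    list(cells = cells, spots = spots, patients = patients,
         ground_truth = ground_truth, config = config),
    class = "synthetic_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

empty_cohort <- function() {
  cells <- dplyr::bind_cols(
    tibble::tibble(cell_id = character(0), patient_id = character(0),
                   spot_id = character(0)),
    empty_cell_block()
  )
  structure(
    list(
      cells = cells,
      spots = tibble::tibble(patient_id = character(0), spot_id = character(0),
                             aligned_area_mm2 = numeric(0),
                             tumor_area_mm2 = numeric(0), qc_pass = logical(0)),
      patients = tibble::tibble(patient_id = character(0), center = character(0),
                                subtype = character(0), uicc8 = integer(0),
                                r_status = integer(0), adjuvant = logical(0),
                                os_months = numeric(0), event = integer(0)),
      ground_truth = tibble::tibble(patient_id = character(0),
                                    archetype = character(0),
                                    true_hazard = numeric(0)),
      config = NULL
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d cells | %d spots | %d patients\n",
              nrow(x$cells), nrow(x$spots), nrow(x$patients)))
  if (nrow(x$patients) > 0) {
    cat("  centers:", paste(unique(x$patients$center), collapse = ", "),
        "| subtypes:", paste(unique(x$patients$subtype), collapse = ", "), "\n")
  }
  invisible(x)
}
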