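# Synthetic cancer-registry generator: latent 7th-edition disease state,
# edition assignment by incidence year, stochastic edition conversion,
# stage-dependent categorical survival and administrative right-censoring.

#' Default stage-conditional survival model
#'
#' Categorical distribution over the five survival categories per
#' 7th-edition stage group. The presets are documented synthetic choices
#' (not registry estimates) with the clinically expected ordering: the
#' probability of surviving at least 24 months decreases monotonically
#' from stage IA to stage IV.
#' @return Matrix, rows = stage groups, columns = survival categories.
#' @export
default_survival_model <- function() {
  m <- rbind(
    IA   = c(0.02, 0.02, 0.04, 0.07, 0.85),
    IB   = c(0.03, 0.04, 0.06, 0.12, 0.75),
    IIA  = c(0.05, 0.05, 0.10, 0.15, 0.65),
    IIB  = c(0.06, 0.07, 0.12, 0.18, 0.57),
    IIIA = c(0.08, 0.10, 0.17, 0.25, 0.40),
    IIIB = c(0.12, 0.15, 0.23, 0.28, 0.22),
    IV   = c(0.25, 0.25, 0.25, 0.17, 0.08)
  )
  colnames(m) <- survival_categories()
  m
}

#' Default latent 7th-edition descriptor distributions
#'
#' Documented synthetic presets for the hidden root nodes, loosely shaped
#' like a clinically staged NSCLC registry mix (a large metastatic
#' fraction, T spread toward higher categories). Not registry estimates.
#' @return Named list of probability vectors for `T_7`, `N_7`, `M_7`.
#' @export
default_latent_distributions <- function() {
  list(
    T_7 = c(T1a = 0.10, T1b = 0.08, T2a = 0.18, T2b = 0.10, T3 = 0.22, T4 = 0.32),
    N_7 = c(N0 = 0.40, N1 = 0.10, N2 = 0.25, N3 = 0.25),
    M_7 = c(M0 = 0.55, M1a = 0.15, M1b = 0.30)
  )
}

#' Simulation configuration
#'
#' Bundles every distribution the registry generator needs. The defaults
#' emulate a national registry extract: 146,084 records over incidence
#' years 1999-2016 with the edition determined by year, conversion CPTs
#' equal to the cross-edition transition priors, stage-monotone categorical
#' survival, administrative censoring at the start of 2017, and the extra
#' rule-reclassification variables collected from 2015 onward.
#'
#' @param n_records Number of records to generate.
#' @param years Incidence years sampled (uniformly unless `year_weights`).
#' @param year_weights Optional sampling weights over `years`.
#' @param edition_mapping Year-to-edition mapping, see [assign_edition()].
#' @param latent Named list of root distributions for `T_7`, `N_7`, `M_7`.
#' @param conversion Named list of `bn_cpt`s used as the generative
#'   edition-conversion truth, shaped like [make_transition_priors()].
#' @param survival_model Stage-by-category probability matrix, see
#'   [default_survival_model()].
#' @param censor_cutoff_year Administrative cutoff: follow-up ends at the
#'   start of this year.
#' @param top_mean_extra_days Mean extra survival (exponential) beyond the
#'   top-category boundary for patients who survive past it.
#' @param extras_start_year First incidence year with the extra variables
#'   (multifocality, tumor size, superior-sulcus involvement).
#' @param extras_rate Fraction of eligible records carrying the extras.
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_records = 146084,
                              years = 1999:2016,
                              year_weights = NULL,
                              edition_mapping = default_edition_mapping(),
                              latent = default_latent_distributions(),
                              conversion = make_transition_priors(),
                              survival_model = default_survival_model(),
                              censor_cutoff_year = 2017,
                              top_mean_extra_days = 600,
                              extras_start_year = 2015,
                              extras_rate = 1,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  for (nd in c("T_7", "N_7", "M_7")) {
    p <- latent[[nd]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("latent distribution for ", nd, " must be a probability vector", call. = FALSE)
    }
  }
  if (any(abs(rowSums(survival_model) - 1) > 1e-9) || any(survival_model < 0)) {
    stop("survival_model rows must be probability vectors", call. = FALSE)
  }
  if (!is.null(year_weights) && length(year_weights) != length(years)) {
    stop("year_weights must match years", call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), years = as.integer(years),
                 year_weights = year_weights, edition_mapping = edition_mapping,
                 latent = latent, conversion = conversion,
                 survival_model = survival_model,
                 censor_cutoff_year = censor_cutoff_year,
                 top_mean_extra_days = top_mean_extra_days,
                 extras_start_year = extras_start_year, extras_rate = extras_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Sample an observed descriptor from a conversion CPT, vectorized by
# grouping on the (edition, hidden-state) parent combination.
sample_converted <- function(cpt, edition, hidden) {
  out <- character(length(edition))
  pidx <- cbind(match(edition, cpt$parent_states$edition),
                match(hidden, cpt$parent_states[[cpt$parents[2]]]))
  row <- cpt_row_index(cpt, pidx)
  for (r in unique(row)) {
    ii <- which(row == r)
    out[ii] <- sample(cpt$states, length(ii), replace = TRUE, prob = cpt$prob[r, ])
  }
  out
}

#' Simulate a synthetic staged-cancer registry
#'
#' Per record: an incidence year is drawn and its TNM edition derived; the
#' latent 7th-edition descriptors are sampled from the root distributions
#' and grouped into the latent stage; observed descriptors are drawn
#' through the conversion CPTs given the edition (the identity when the
#' edition is 7) and grouped with the edition's table; a survival category
#' is drawn given the latent stage, a death day consistent with it, and an
#' administrative censoring day from the incidence year — so the observed
#' survival category is missing exactly for patients alive with less than
#' 731 days of follow-up. Records from `extras_start_year` onward carry
#' multifocality, tumor size and superior-sulcus fields consistent with
#' their latent T.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (observed data frame, as [read_registry()]
#'   returns) and `truth` (per-record latent `T_7`, `N_7`, `M_7`, `TNM_7`
#'   and the uncensored survival category).
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  boundaries <- default_survival_boundaries()
  categories <- survival_categories(boundaries)
  with_seed(config$seed, {
    n <- config$n_records
    year <- sample(config$years, n, replace = TRUE, prob = config$year_weights)
    edition <- assign_edition(year, config$edition_mapping)

    draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    t7 <- draw(config$latent$T_7)
    n7 <- draw(config$latent$N_7)
    m7 <- draw(config$latent$M_7)
    tnm7 <- stage_group(t7, n7, m7, "7")

    t_obs <- sample_converted(config$conversion$T_567, edition, t7)
    n_obs <- sample_converted(config$conversion$N_567, edition, n7)
    m_obs <- sample_converted(config$conversion$M_567, edition, m7)
    stage_obs <- stage_group(t_obs, n_obs, m_obs, edition)

    # survival: category given latent stage, then a consistent death day
    cat_idx <- integer(n)
    for (st in rownames(config$survival_model)) {
      ii <- which(tnm7 == st)
      if (length(ii)) {
        cat_idx[ii] <- sample.int(ncol(config$survival_model), length(ii),
                                  replace = TRUE, prob = config$survival_model[st, ])
      }
    }
    # integer day ranges per category: [ceil(lo), ceil(hi) - 1] keeps the
    # realized death day inside the sampled category after discretization
    day_bounds <- ceiling(c(0, boundaries) * DAYS_PER_MONTH)
    top <- cat_idx == length(categories)
    lo <- day_bounds[pmin(cat_idx, length(categories) - 1L)]
    hi <- day_bounds[pmin(cat_idx, length(categories) - 1L) + 1L] - 1L
    death_day <- lo + floor(stats::runif(n) * (hi - lo + 1))
    death_day[top] <- day_bounds[length(day_bounds)] +
      round(stats::rexp(sum(top), 1 / config$top_mean_extra_days))
    censor_day <- pmax(0, (config$censor_cutoff_year - year - stats::runif(n)) * 365.25)
    dead <- death_day <= censor_day
    follow_up <- ifelse(dead, death_day, floor(censor_day))
    vital <- ifelse(dead, "dead", "alive")
    survival <- discretize_survival(follow_up, vital, boundaries)

    # extras, consistent with the latent T
    has_extras <- year >= config$extras_start_year & stats::runif(n) < config$extras_rate
    size_range <- list(T1a = c(5, 20), T1b = c(20, 30), T2a = c(30, 50),
                       T2b = c(50, 70), T3 = c(30, 90), T4 = c(30, 100))
    size <- rep(NA_real_, n)
    multifocal <- rep(NA, n)
    sulcus <- rep(NA, n)
    for (tt in names(size_range)) {
      ii <- which(has_extras & t7 == tt)
      if (!length(ii)) next
      size[ii] <- round(stats::runif(length(ii), size_range[[tt]][1], size_range[[tt]][2]))
      mf_p <- switch(tt, T4 = 0.13, T3 = 0.05, 0)
      multifocal[ii] <- stats::runif(length(ii)) < mf_p
      sc_p <- if (tt %in% c("T3", "T4")) 0.04 else 0
      sulcus[ii] <- stats::runif(length(ii)) < sc_p
    }

    records <- data.frame(
      id = seq_len(n),
      incidence_year = year,
      edition = edition,
      t = t_obs, n = n_obs, m = m_obs,
      stage = stage_obs,
      follow_up_days = as.integer(follow_up),
      vital_status = vital,
      survival = survival,
      multifocal = multifocal,
      tumor_size_mm = size,
      sulcus_superior = sulcus,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      id = seq_len(n),
      T_7 = t7, N_7 = n7, M_7 = m7, TNM_7 = tnm7,
      survival_true = categories[cat_idx],
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Random train/test split
#'
#' Disjoint, exhaustive, reproducible split of a record table.
#'
#' @param records Data frame.
#' @param train_fraction Proportion assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(records, train_fraction = 0.8, seed) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(records)
    n_train <- round(n * train_fraction)
    idx <- sample.int(n, n_train)
    list(train = records[idx, , drop = FALSE],
         test = records[-idx, , drop = FALSE])
  })
}
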