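#' Disease groups tracked by the package
#'
#' The three chronic disease groups and the ICD-10 code ranges that define
#' them: diabetes (E10-E14), cerebrovascular disease (I61-I69) and ischemic
#' heart disease (I20-I25).
#'
#' @format A character vector of the three disease names, in canonical order.
#' @export
DISEASES <- c("diabetes", "cerebrovascular", "ischemic")

# ICD-10 roots per disease group; synthetic diagnosis codes are "<root>.<d>".
disease_code_roots <- function() {
  list(
    diabetes        = sprintf("E%02d", 10:14),
    cerebrovascular = sprintf("I%02d", 61:69),
    ischemic        = sprintf("I%02d", 20:25)
  )
}

# Which disease group (if any) an ICD-10-style code string belongs to.
code_disease_group <- function(codes) {
  roots <- disease_code_roots()
  out <- rep(NA_character_, length(codes))
  pre <- substr(codes, 1L, 3L)
  for (d in names(roots)) out[pre %in% roots[[d]]] <- d
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated claims cohort: sex-specific
#' demographic distributions, multi-label disease prevalence with a shared
#' latent comorbidity risk, a truncated negative-binomial visit-count model,
#' and per-disease diagnosis/prescription code pools whose sampling weight
#' (`signal_strength`) controls how strongly visit content separates disease
#' groups.
#'
#' Demographic defaults follow a Korean national claims cohort of patients
#' with diabetes, cerebrovascular or ischemic heart disease: 56% male; male
#' age 57.8 (SD 23.4) years, SBP 126.4 (27.1) mmHg, DBP 78.8 (12.6) mmHg,
#' BMI 22.3 (5.8) kg/m^2; female age 60.5 (21.5), SBP 131.8 (24.8),
#' DBP 81.8 (14.2), BMI 23.1 (4.2).
#'
#' @param n_patients number of patients to simulate (>= 2).
#' @param prevalence named numeric of length 3: marginal probability of each
#'   disease before conditioning on carrying at least one.
#' @param comorbidity nonnegative scalar; loading of the shared latent risk on
#'   each disease's log-odds. 0 makes diseases independent.
#' @param demographics list with `male` and `female` entries, each a named list
#'   of `mean`/`sd` pairs for `age`, `sbp`, `dbp`, `bmi`.
#' @param p_male probability a patient is male.
#' @param visit_nb_size,visit_nb_mu negative-binomial size and mean for
#'   per-patient visit counts, truncated to `[1, max_visits]`.
#' @param max_visits,max_dx generation-time caps mirroring the cohort
#'   exclusion rules (at most 200 visits; at most 12 diagnosis codes a visit).
#' @param codes_per_pool diagnosis codes available per disease pool (<= 50 for
#'   diabetes, <= 90 cerebrovascular, <= 60 ischemic given one decimal digit).
#' @param n_background_codes diagnosis codes in the disease-neutral pool.
#' @param rx_per_pool,n_background_rx prescription-code pool sizes.
#' @param dx_rate Poisson rate for extra diagnosis codes per visit (each visit
#'   gets 1 + Pois(dx_rate), capped at `max_dx`).
#' @param rx_rate Poisson rate for prescription codes per visit.
#' @param signal_strength probability that a diagnosis code is drawn from one
#'   of the patient's active-disease pools rather than the background pool.
#' @param risk_marker_rate per-visit probability that a patient outside the
#'   normal blood-pressure (resp. BMI) group emits a stage-specific
#'   hypertension (resp. weight-status) diagnosis code. These marker codes
#'   are how BP and BMI strata surface in visit content, as they do in real
#'   claims data; 0 removes the channel entirely.
#' @param bp_bmi_coupling logical; couple blood pressure to age/vascular
#'   disease and BMI to diabetes so that the BP and BMI label categories are
#'   partially predictable from visit content.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500L,
                          prevalence = c(diabetes = 0.45, cerebrovascular = 0.30,
                                         ischemic = 0.35),
                          comorbidity = 1.0,
                          demographics = default_demographics(),
                          p_male = 0.56,
                          visit_nb_size = 2,
                          visit_nb_mu = 30,
                          max_visits = 200L,
                          max_dx = 12L,
                          codes_per_pool = 30L,
                          n_background_codes = 100L,
                          rx_per_pool = 20L,
                          n_background_rx = 50L,
                          dx_rate = 2,
                          rx_rate = 1.5,
                          signal_strength = 0.85,
                          risk_marker_rate = 0.6,
                          bp_bmi_coupling = TRUE,
                          seed = 1L) {
  if (!is_count(n_patients, 2L)) stop_config("n_patients", "must be an integer >= 2")
  if (length(prevalence) != 3L || !is_prob(prevalence)) {
    stop_config("prevalence", "must be 3 probabilities in [0, 1]")
  }
  names(prevalence) <- DISEASES
  if (!is.numeric(comorbidity) || comorbidity < 0) {
    stop_config("comorbidity", "must be a nonnegative number")
  }
  if (!is_prob(p_male)) stop_config("p_male", "must be in [0, 1]")
  if (!is_prob(signal_strength)) stop_config("signal_strength", "must be in [0, 1]")
  if (!is_prob(risk_marker_rate)) stop_config("risk_marker_rate", "must be in [0, 1]")
  if (!is.numeric(visit_nb_size) || visit_nb_size <= 0) {
    stop_config("visit_nb_size", "must be > 0")
  }
  if (!is.numeric(visit_nb_mu) || visit_nb_mu <= 0) stop_config("visit_nb_mu", "must be > 0")
  if (!is_count(max_visits)) stop_config("max_visits", "must be a positive integer")
  if (!is_count(max_dx)) stop_config("max_dx", "must be a positive integer")
  for (fld in c("codes_per_pool", "n_background_codes", "rx_per_pool", "n_background_rx")) {
    if (!is_count(get(fld))) stop_config(fld, "must be a positive integer")
  }
  for (sx in c("male", "female")) {
    dd <- demographics[[sx]]
    if (is.null(dd)) stop_config("demographics", paste("missing entry", sx))
    for (v in c("age", "sbp", "dbp", "bmi")) {
      if (is.null(dd[[v]]) || length(dd[[v]]) != 2L || dd[[v]][2] <= 0) {
        stop_config("demographics", sprintf("%s$%s must be c(mean, sd) with sd > 0", sx, v))
      }
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    comorbidity = comorbidity, demographics = demographics, p_male = p_male,
    visit_nb_size = visit_nb_size, visit_nb_mu = visit_nb_mu,
    max_visits = as.integer(max_visits), max_dx = as.integer(max_dx),
    codes_per_pool = as.integer(codes_per_pool),
    n_background_codes = as.integer(n_background_codes),
    rx_per_pool = as.integer(rx_per_pool),
    n_background_rx = as.integer(n_background_rx),
    dx_rate = dx_rate, rx_rate = rx_rate,
    signal_strength = signal_strength, risk_marker_rate = risk_marker_rate,
    bp_bmi_coupling = isTRUE(bp_bmi_coupling),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_demographics <- function() {
  list(
    male   = list(age = c(57.8, 23.4), sbp = c(126.4, 27.1),
                  dbp = c(78.8, 12.6), bmi = c(22.3, 5.8)),
    female = list(age = c(60.5, 21.5), sbp = c(131.8, 24.8),
                  dbp = c(81.8, 14.2), bmi = c(23.1, 4.2))
  )
}

build_code_pools <- function(config) {
  roots <- disease_code_roots()
  dx <- lapply(roots, function(r) {
    all <- as.vector(outer(r, 0:9, function(a, b) paste0(a, ".", b)))
    all[seq_len(min(length(all), config$codes_per_pool))]
  })
  bg_dx <- sprintf("Z%02d.%d", rep(0:49, each = 2), rep(0:1, 50))[
    seq_len(config$n_background_codes)]
  rx <- lapply(names(roots), function(d) {
    sprintf("RX-%s-%03d", toupper(substr(d, 1, 3)), seq_len(config$rx_per_pool))
  })
  names(rx) <- names(roots)
  bg_rx <- sprintf("RX-BG-%03d", seq_len(config$n_background_rx))
  # stage/status marker codes: hypertension (I10 essential, I15 stage-2 here)
  # and weight-status (R63 underweight, E66 overweight); none fall in the
  # three tracked disease ranges
  markers <- list(
    bp2 = sprintf("I10.%d", 0:4), bp3 = sprintf("I15.%d", 0:4),
    bmi1 = sprintf("R63.%d", 0:4), bmi3 = sprintf("E66.%d", 0:4)
  )
  list(dx = dx, bg_dx = bg_dx, rx = rx, bg_rx = bg_rx, markers = markers)
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates `config$n_patients` patients, each with demographics, three
#' binary disease flags (every patient carries at least one of the three
#' diseases, as in a disease-filtered claims extract), and an ordered
#' variable-length visit sequence. Each visit carries demographic tokens (sex,
#' age group), 1..`max_dx` diagnosis codes and 0+ prescription codes, with
#' diagnosis codes drawn preferentially from the pools of the patient's active
#' diseases so that same-disease patients are statistically close in code
#' space. Fully deterministic given the config (which includes the seed).
#'
#' @param config a [cohort_config()].
#' @return a list of `patient_record` objects, classed `patient_cohort`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_config("config", "must be created by cohort_config()")
  }
  pools <- build_code_pools(config)
  with_seed(config$seed, {
    n <- config$n_patients
    sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    z <- stats::rnorm(n)
    logit <- stats::qlogis(pmin(pmax(config$prevalence, 1e-6), 1 - 1e-6))
    flags <- matrix(FALSE, n, 3L, dimnames = list(NULL, DISEASES))
    for (k in 1:3) {
      p <- stats::plogis(logit[k] + config$comorbidity * z)
      flags[, k] <- stats::runif(n) < p
    }
    if (any(config$prevalence > 0)) {
      none <- which(rowSums(flags) == 0L)
      for (i in none) {
        # disease-filtered cohort: assign one disease by prevalence weight
        k <- sample.int(3L, 1L, prob = config$prevalence + 1e-12)
        flags[i, k] <- TRUE
      }
    }
    records <- vector("list", n)
    for (i in seq_len(n)) {
      dd <- config$demographics[[sex[i]]]
      age <- round(stats::rnorm(1, dd$age[1], dd$age[2]))
      sbp <- stats::rnorm(1, dd$sbp[1], dd$sbp[2])
      dbp <- stats::rnorm(1, dd$dbp[1], dd$dbp[2])
      bmi <- stats::rnorm(1, dd$bmi[1], dd$bmi[2])
      if (config$bp_bmi_coupling) {
        vas <- sum(flags[i, c("cerebrovascular", "ischemic")])
        sbp <- sbp + 9 * vas + 0.25 * (age - dd$age[1])
        dbp <- dbp + 5 * vas + 0.10 * (age - dd$age[1])
        bmi <- bmi + 2.5 * flags[i, "diabetes"]
      }
      age <- min(max(age, 0L), 110L)
      bmi <- round(min(max(bmi, 10.5), 59.5), 1)
      dbp <- round(max(dbp, 40), 1)
      sbp <- round(sbp, 1)
      if (sbp <= dbp) sbp <- dbp + 5
      bp_group <- bin_bp(sbp, dbp)
      bmi_group <- bin_bmi(bmi)
      marker_pools <- list()
      if (bp_group == 2L) marker_pools <- c(marker_pools, list(pools$markers$bp2))
      if (bp_group == 3L) marker_pools <- c(marker_pools, list(pools$markers$bp3))
      if (bmi_group == 1L) marker_pools <- c(marker_pools, list(pools$markers$bmi1))
      if (bmi_group == 3L) marker_pools <- c(marker_pools, list(pools$markers$bmi3))
      active <- DISEASES[flags[i, ]]
      n_visits <- 0L
      while (n_visits < 1L || n_visits > config$max_visits) {
        n_visits <- stats::rnbinom(1, size = config$visit_nb_size, mu = config$visit_nb_mu)
      }
      visits <- vector("list", n_visits)
      for (v in seq_len(n_visits)) {
        n_dx <- min(1L + stats::rpois(1, config$dx_rate), config$max_dx)
        from_pool <- stats::runif(n_dx) < config$signal_strength & length(active) > 0L
        dx <- character(n_dx)
        for (j in seq_len(n_dx)) {
          dx[j] <- if (from_pool[j]) {
            pool <- pools$dx[[sample(active, 1L)]]
            pool[sample.int(length(pool), 1L)]
          } else {
            pools$bg_dx[sample.int(length(pools$bg_dx), 1L)]
          }
        }
        for (mp in marker_pools) {
          if (stats::runif(1) < config$risk_marker_rate && length(dx) < config$max_dx) {
            dx <- c(dx, mp[sample.int(length(mp), 1L)])
          }
        }
        n_rx <- stats::rpois(1, config$rx_rate)
        rx <- character(0)
        if (n_rx > 0L) {
          rx <- vapply(seq_len(n_rx), function(j) {
            if (stats::runif(1) < config$signal_strength && length(active) > 0L) {
              pool <- pools$rx[[sample(active, 1L)]]
              pool[sample.int(length(pool), 1L)]
            } else {
              pools$bg_rx[sample.int(length(pools$bg_rx), 1L)]
            }
          }, character(1))
        }
        visits[[v]] <- list(ordinal = v, diagnosis_codes = dx, prescription_codes = rx)
      }
      # guarantee flag/code consistency: every active disease appears at least once
      seen <- unique(stats::na.omit(code_disease_group(
        unlist(lapply(visits, `[[`, "diagnosis_codes"), use.names = FALSE))))
      for (d in setdiff(active, seen)) {
        v <- sample.int(n_visits, 1L)
        dxv <- visits[[v]]$diagnosis_codes
        pool <- pools$dx[[d]]
        if (length(dxv) < config$max_dx) {
          visits[[v]]$diagnosis_codes <- c(dxv, pool[sample.int(length(pool), 1L)])
        } else {
          # replace a background code if present, else the last code
          bg <- which(is.na(code_disease_group(dxv)))
          slot <- if (length(bg)) bg[1] else length(dxv)
          visits[[v]]$diagnosis_codes[slot] <- pool[sample.int(length(pool), 1L)]
        }
      }
      records[[i]] <- patient_record(
        patient_id = sprintf("P%05d", i),
        demographics = list(age = as.integer(age), sex = sex[i],
                            sbp = as.numeric(sbp), dbp = as.numeric(dbp),
                            bmi = as.numeric(bmi)),
        disease_flags = as.list(flags[i, ]),
        visits = visits
      )
    }
    structure(records, class = "patient_cohort")
  })
}

#' Construct and validate a single patient record
#'
#' @param patient_id opaque id string.
#' @param demographics named list: `age` (integer years, 0-110), `sex`
#'   ("male"/"female"), `sbp`/`dbp` (mmHg, `sbp > dbp > 0`), `bmi`
#'   (kg/m^2 in (10, 60)).
#' @param disease_flags named list of 3 logicals (diabetes, cerebrovascular,
#'   ischemic).
#' @param visits list of visits, each `list(ordinal, diagnosis_codes,
#'   prescription_codes)`, sorted by ordinal, `diagnosis_codes` non-empty.
#' @param check validate invariants (default TRUE).
#' @return a `patient_record`.
#' @export
patient_record <- function(patient_id, demographics, disease_flags, visits,
                           check = TRUE) {
  rec <- structure(list(patient_id = patient_id, demographics = demographics,
                        disease_flags = disease_flags, visits = visits),
                   class = "patient_record")
  if (check) validate_patient_record(rec)
  rec
}

validate_patient_record <- function(rec) {
  d <- rec$demographics
  if (!d$sex %in% c("male", "female")) stop("sex must be 'male' or 'female'")
  if (d$age < 0 || d$age > 110) stop("age out of [0, 110]")
  if (!(d$sbp > d$dbp && d$dbp > 0)) stop("require sbp > dbp > 0")
  if (!(d$bmi > 10 && d$bmi < 60)) stop("bmi out of (10, 60)")
  ords <- vapply(rec$visits, `[[`, numeric(1), "ordinal")
  if (is.unsorted(ords, strictly = TRUE)) stop("visits must be sorted by ordinal")
  if (any(vapply(rec$visits, function(v) length(v$diagnosis_codes) == 0L, logical(1)))) {
    stop("every visit needs at least one diagnosis code")
  }
  invisible(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  d <- x$demographics
  cat(sprintf("<patient_record %s: %s, age %d, %d visits, diseases: %s>\n",
              x$patient_id, d$sex, d$age, length(x$visits),
              paste(DISEASES[unlist(x$disease_flags)], collapse = "+") ))
  invisible(x)
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat(sprintf("<patient_cohort: %d patients>\n", length(x)))
  invisible(x)
}

#' Check that disease flags agree with diagnosis codes
#'
#' A flag is consistent when the patient has the flag set if and only if at
#' least one diagnosis code from the matching ICD-10 range appears in some
#' visit.
#'
#' @param record a `patient_record`.
#' @return named logical vector of per-disease consistency.
#' @export
disease_flag_consistency <- function(record) {
  codes <- unlist(lapply(record$visits, `[[`, "diagnosis_codes"), use.names = FALSE)
  seen <- code_disease_group(codes)
  out <- vapply(DISEASES, function(d) {
    isTRUE(record$disease_flags[[d]]) == any(seen == d, na.rm = TRUE)
  }, logical(1))
  out
}

#' Apply cohort exclusion rules
#'
#' Removes extreme patients before representation: a patient is excluded when
#' they have more than `max_visits` visits, or when any single visit carries
#' more than `max_dx` diagnosis codes. A patient failing both rules is counted
#' under "visits". Idempotent.
#'
#' @param cohort a `patient_cohort` (or plain list of `patient_record`s).
#' @param max_dx maximum diagnosis codes per visit (default 12).
#' @param max_visits maximum visits per patient (default 200).
#' @return list with `cohort` (filtered, same class) and `report`, a
#'   data.frame with columns `reason` ("visits", "diagnoses") and `n_removed`,
#'   plus attributes `n_input`/`n_kept`.
#' @export
apply_exclusion_filters <- function(cohort, max_dx = 12L, max_visits = 200L) {
  too_many_visits <- vapply(cohort, function(r) length(r$visits) > max_visits, logical(1))
  too_many_dx <- vapply(cohort, function(r) {
    any(vapply(r$visits, function(v) length(v$diagnosis_codes), integer(1)) > max_dx)
  }, logical(1))
  drop_dx <- too_many_dx & !too_many_visits
  keep <- !(too_many_visits | too_many_dx)
  report <- data.frame(
    reason = c("visits", "diagnoses"),
    n_removed = c(sum(too_many_visits), sum(drop_dx)),
    stringsAsFactors = FALSE
  )
  attr(report, "n_input") <- length(cohort)
  attr(report, "n_kept") <- sum(keep)
  out <- cohort[keep]
  class(out) <- class(cohort)
  list(cohort = out, report = report)
}

#' Write / read a cohort as JSON Lines
#'
#' One patient per line; schema version "patsim-cohort-1". Round-trips exactly.
#'
#' @param cohort a `patient_cohort`.
#' @param path file path.
#' @return `write_cohort_jsonl` returns `path` invisibly; `read_cohort_jsonl`
#'   returns a `patient_cohort`.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in cohort) {
    obj <- list(
      schema = "patsim-cohort-1",
      patient_id = rec$patient_id,
      demographics = rec$demographics,
      disease_flags = rec$disease_flags,
      visits = lapply(rec$visits, function(v) {
        list(ordinal = v$ordinal,
             dx = as.list(v$diagnosis_codes),
             rx = as.list(v$prescription_codes))
      })
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  records <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (!identical(obj$schema, "patsim-cohort-1")) {
      stop("unrecognized cohort schema: ", obj$schema %||% "<missing>")
    }
    d <- obj$demographics
    patient_record(
      patient_id = obj$patient_id,
      demographics = list(age = as.integer(d$age), sex = as.character(d$sex),
                          sbp = as.numeric(d$sbp), dbp = as.numeric(d$dbp),
                          bmi = as.numeric(d$bmi)),
      disease_flags = lapply(obj$disease_flags, isTRUE),
      visits = lapply(obj$visits, function(v) {
        list(ordinal = v$ordinal,
             diagnosis_codes = as.character(unlist(v$dx)),
             prescription_codes = as.character(unlist(v$rx)))
      })
    )
  })
  structure(records, class = "patient_cohort")
}
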