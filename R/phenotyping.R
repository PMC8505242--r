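#' Phenotyping rule parameters
#'
#' All day thresholds of the MDD/TRD algorithm surface here with their
#' default values: a qualifying treatment episode must span at least 6 weeks
#' (42 days), consecutive prescriptions at most 14 weeks (98 days) apart are
#' chained into one episode, the same 98-day ceiling limits the gap between
#' two drugs at a switch, and two episodes overlapping by more than 30 days
#' count as a combination rather than a switch. Comparisons are inclusive
#' (`<=` for gaps, `>=` for durations, `>` for the combination overlap).
#'
#' @param min_depression_codes 1 or 2; number of depression diagnostic codes
#'   on distinct dates required for MDD case status. The stringent default of
#'   2 guards against one-off miscoding; 1 reproduces the broad definition.
#' @param gap_days maximum days between consecutive prescriptions of one
#'   drug (episode chaining) and between two drugs at a switch.
#' @param min_episode_days minimum episode span (last minus first issue
#'   date) for the episode to qualify for switch detection.
#' @param overlap_days overlap (days) beyond which two episodes are a
#'   combination/augmentation rather than a switch.
#' @param control_screening `"all_psychiatric"` (controls must have no code
#'   in any psychiatric category) or `"mdd_only"` (controls screened only
#'   for depression codes, the sensitivity-analysis definition).
#' @return list of class `phenotype_params`.
#' @export
phenotype_params <- function(min_depression_codes = 2L,
                             gap_days = 98L,
                             min_episode_days = 42L,
                             overlap_days = 30L,
                             control_screening = c("all_psychiatric", "mdd_only")) {
  control_screening <- match.arg(control_screening)
  stopifnot(min_depression_codes %in% c(1L, 2L),
            gap_days > 0, min_episode_days > 0, overlap_days > 0)
  structure(list(
    min_depression_codes = as.integer(min_depression_codes),
    gap_days = as.numeric(gap_days),
    min_episode_days = as.numeric(min_episode_days),
    overlap_days = as.numeric(overlap_days),
    control_screening = control_screening
  ), class = "phenotype_params")
}

#' Classify one patient's MDD status from coded clinical events
#'
#' CASE: at least `min_depression_codes` depression codes on distinct dates
#' and no code in an exclusion category (bipolar, psychotic, substance use).
#' EXCLUDED: any exclusion-category code, regardless of depression codes.
#' CONTROL: no psychiatric code at all (or, under `"mdd_only"` screening, no
#' depression code). SUBTHRESHOLD: everything in between — typically a single
#' depression code or another psychiatric diagnosis — usable as neither case
#' nor clean control.
#'
#' @param events data.frame of one patient's clinical events with a
#'   `category` column (see [read_clinical_table]); zero rows allowed.
#' @param params a [phenotype_params].
#' @return one of `"CASE"`, `"CONTROL"`, `"EXCLUDED"`, `"SUBTHRESHOLD"`.
#' @export
classify_mdd <- function(events, params = phenotype_params()) {
  if (nrow(events) == 0L) return("CONTROL")
  cat_ <- events$category
  if (any(cat_ %in% EXCLUSION_CATEGORIES)) return("EXCLUDED")
  dep_dates <- unique(events$event_date[cat_ == "DEPRESSION"])
  if (length(dep_dates) >= params$min_depression_codes) return("CASE")
  screened <- if (params$control_screening == "all_psychiatric")
    PSYCHIATRIC_CATEGORIES else "DEPRESSION"
  if (any(cat_ %in% screened)) return("SUBTHRESHOLD")
  "CONTROL"
}

#' Chain one patient's prescriptions into same-drug episodes
#'
#' Per drug, issues sorted by date are linked into runs where each
#' consecutive gap is at most `gap_days`; a longer gap starts a new episode.
#' An episode's duration is last minus first issue date in days, so a lone
#' prescription has duration 0 and can never satisfy the 6-week rule.
#'
#' @param prescriptions data.frame of one patient's prescription events
#'   (columns `patient_id`, `issue_date`, `drug_id`, `drug_class`).
#' @param params a [phenotype_params].
#' @return data.frame of episodes sorted by `start_date`, with columns
#'   `patient_id`, `drug_id`, `drug_class`, `start_date`, `end_date`,
#'   `n_prescriptions`, `duration_days`.
#' @export
build_drug_episodes <- function(prescriptions, params = phenotype_params()) {
  empty <- data.frame(
    patient_id = character(), drug_id = character(), drug_class = character(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    n_prescriptions = integer(), duration_days = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(prescriptions) == 0L) return(empty)
  p <- prescriptions[order(prescriptions$drug_id, prescriptions$issue_date), ,
                     drop = FALSE]
  gaps <- c(Inf, diff(as.numeric(p$issue_date)))
  new_run <- p$drug_id != c("", p$drug_id[-nrow(p)]) | gaps > params$gap_days
  run <- cumsum(new_run)
  eps <- do.call(rbind, lapply(split(seq_len(nrow(p)), run), function(i) {
    data.frame(
      patient_id = p$patient_id[i[1L]],
      drug_id = p$drug_id[i[1L]],
      drug_class = p$drug_class[i[1L]],
      start_date = min(p$issue_date[i]),
      end_date = max(p$issue_date[i]),
      n_prescriptions = length(i),
      duration_days = as.numeric(max(p$issue_date[i]) - min(p$issue_date[i])),
      stringsAsFactors = FALSE
    )
  }))
  eps <- eps[order(eps$start_date, eps$end_date, eps$drug_id), , drop = FALSE]
  rownames(eps) <- NULL
  eps
}

episode_overlap_days <- function(start1, end1, start2, end2) {
  as.numeric(pmin(end1, end2) - pmax(start1, start2))
}

#' Detect switches between antidepressant episodes
#'
#' From the chronological sequence of qualifying antidepressant episodes
#' (duration at least `min_episode_days`), each adjacent pair of episodes of
#' different drugs is a switch when the gap from the end of the first to the
#' start of the second is at most `gap_days` and the two date ranges do not
#' overlap by more than `overlap_days` (such pairs are combinations, analysed
#' separately — a switch implies discontinuation). A-to-B-to-A yields two
#' switches: only adjacent drugs need to differ, drug novelty is not
#' required.
#'
#' @param episodes data.frame from [build_drug_episodes]; non-antidepressant
#'   rows are ignored.
#' @param params a [phenotype_params].
#' @return data.frame of switches (possibly zero rows) with columns
#'   `patient_id`, `from_drug`, `to_drug`, `from_end`, `to_start`,
#'   `gap_days`.
#' @export
detect_switches <- function(episodes, params = phenotype_params()) {
  empty <- data.frame(
    patient_id = character(), from_drug = character(), to_drug = character(),
    from_end = as.Date(character()), to_start = as.Date(character()),
    gap_days = numeric(), stringsAsFactors = FALSE
  )
  q <- episodes[episodes$drug_class == "ANTIDEPRESSANT" &
                  episodes$duration_days >= params$min_episode_days, ,
                drop = FALSE]
  if (nrow(q) < 2L) return(empty)
  q <- q[order(q$start_date, q$end_date, q$drug_id), , drop = FALSE]
  a <- q[-nrow(q), , drop = FALSE]
  b <- q[-1L, , drop = FALSE]
  gap <- as.numeric(b$start_date - a$end_date)
  ovl <- episode_overlap_days(a$start_date, a$end_date, b$start_date, b$end_date)
  is_switch <- a$drug_id != b$drug_id & gap <= params$gap_days &
    ovl <= params$overlap_days
  out <- data.frame(
    patient_id = a$patient_id[is_switch],
    from_drug = a$drug_id[is_switch],
    to_drug = b$drug_id[is_switch],
    from_end = a$end_date[is_switch],
    to_start = b$start_date[is_switch],
    gap_days = gap[is_switch],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify treatment resistance for one patient
#'
#' TRD status is only defined for MDD cases with at least one antidepressant
#' prescription; everyone else is `NOT_APPLICABLE`. Among treated cases, TRD
#' requires at least two qualifying switches between different
#' antidepressants.
#'
#' @param mdd_status value from [classify_mdd].
#' @param treated logical, any antidepressant prescription on record.
#' @param n_switches switch count from [detect_switches].
#' @return one of `"TRD"`, `"NON_TRD"`, `"NOT_APPLICABLE"`.
#' @export
classify_trd <- function(mdd_status, treated, n_switches) {
  if (!identical(mdd_status, "CASE") || !isTRUE(treated)) return("NOT_APPLICABLE")
  if (n_switches >= 2L) "TRD" else "NON_TRD"
}

#' Proportion of adequate antidepressant prescription intervals
#'
#' A compliance proxy: all of a patient's antidepressant prescriptions (any
#' drug, pooled) are sorted by date, and the fraction of consecutive-pair
#' intervals of at most `gap_days` (14 weeks) is returned. Not circular with
#' the TRD definition, which only constrains the interval between different
#' drugs at a switch. Missing (`NA`) with fewer than two prescriptions.
#'
#' @param prescriptions one patient's prescription events; only rows with
#'   `drug_class == "ANTIDEPRESSANT"` are used.
#' @param params a [phenotype_params].
#' @return proportion in `[0, 1]`, or `NA`.
#' @export
adequate_interval_proportion <- function(prescriptions,
                                         params = phenotype_params()) {
  d <- sort(prescriptions$issue_date[prescriptions$drug_class == "ANTIDEPRESSANT"])
  if (length(d) < 2L) return(NA_real_)
  gaps <- diff(as.numeric(d))
  mean(gaps <= params$gap_days)
}

#' Combination and augmentation flags for one patient
#'
#' Combination: two episodes of different antidepressants whose date ranges
#' overlap by more than `overlap_days`. Augmentation: an antipsychotic or
#' mood-stabilizer episode overlapping an antidepressant episode by more
#' than `overlap_days`. Episodes are built with the same 98-day chaining as
#' the switch logic.
#'
#' @param prescriptions one patient's prescription events, all drug classes.
#' @param params a [phenotype_params].
#' @return list with logical `combination` and `augmentation`.
#' @export
detect_combination_augmentation <- function(prescriptions,
                                            params = phenotype_params()) {
  eps <- build_drug_episodes(prescriptions, params)
  ad <- eps[eps$drug_class == "ANTIDEPRESSANT", , drop = FALSE]
  aug <- eps[eps$drug_class %in% c("ANTIPSYCHOTIC", "MOOD_STABILIZER"), ,
             drop = FALSE]
  combination <- FALSE
  if (nrow(ad) >= 2L) {
    for (i in seq_len(nrow(ad) - 1L)) {
      ovl <- episode_overlap_days(ad$start_date[i], ad$end_date[i],
                                  ad$start_date[-seq_len(i)], ad$end_date[-seq_len(i)])
      diff_drug <- ad$drug_id[-seq_len(i)] != ad$drug_id[i]
      if (any(diff_drug & ovl > params$overlap_days)) {
        combination <- TRUE
        break
      }
    }
  }
  augmentation <- FALSE
  if (nrow(ad) >= 1L && nrow(aug) >= 1L) {
    for (i in seq_len(nrow(ad))) {
      ovl <- episode_overlap_days(ad$start_date[i], ad$end_date[i],
                                  aug$start_date, aug$end_date)
      if (any(ovl > params$overlap_days)) {
        augmentation <- TRUE
        break
      }
    }
  }
  list(combination = combination, augmentation = augmentation)
}

#' Record counts and per-year record density for one patient
#'
#' Returns raw and distinct-date counts of clinical and prescription records
#' and their ratio to the observation span in years. The span is (last
#' record minus first record)/365.25 across both tables, floored at one
#' year, so a patient whose records fall on a single date gets a rate equal
#' to the distinct-date count.
#'
#' @param events one patient's clinical events.
#' @param prescriptions one patient's prescription events.
#' @return list with `n_clinical_records`, `n_prescription_records`,
#'   `n_clinical_dates`, `n_prescription_dates`, `span_years`,
#'   `records_per_year` (distinct dates per year of observation).
#' @export
record_density <- function(events, prescriptions) {
  n_clin <- nrow(events)
  n_rx <- nrow(prescriptions)
  clin_dates <- unique(events$event_date)
  rx_dates <- unique(prescriptions$issue_date)
  all_dates <- c(events$event_date, prescriptions$issue_date)
  if (length(all_dates) == 0L) {
    return(list(n_clinical_records = 0L, n_prescription_records = 0L,
                n_clinical_dates = 0L, n_prescription_dates = 0L,
                span_years = 0, records_per_year = 0))
  }
  span <- max(1, as.numeric(max(all_dates) - min(all_dates)) / 365.25)
  n_dates <- length(unique(all_dates))
  list(
    n_clinical_records = n_clin,
    n_prescription_records = n_rx,
    n_clinical_dates = length(clin_dates),
    n_prescription_dates = length(rx_dates),
    span_years = span,
    records_per_year = n_dates / span
  )
}

#' Calendar-year prescribing trends
#'
#' Cohort-level histogram of prescriptions per calendar year, by drug and by
#' pharmacological class. Class totals are by construction the sum of their
#' member drugs' totals.
#'
#' @param prescriptions cohort prescription events.
#' @return list of two data.frames: `by_drug` (`year`, `drug_id`, `n`) and
#'   `by_class` (`year`, `drug_class`, `n`).
#' @export
annual_trends <- function(prescriptions) {
  if (nrow(prescriptions) == 0L) {
    return(list(
      by_drug = data.frame(year = integer(), drug_id = character(),
                           n = integer(), stringsAsFactors = FALSE),
      by_class = data.frame(year = integer(), drug_class = character(),
                            n = integer(), stringsAsFactors = FALSE)
    ))
  }
  year <- as.integer(format(prescriptions$issue_date, "%Y"))
  by_drug <- as.data.frame(table(year = year, drug_id = prescriptions$drug_id),
                           stringsAsFactors = FALSE)
  by_drug <- by_drug[by_drug$Freq > 0L, , drop = FALSE]
  by_drug <- data.frame(year = as.integer(by_drug$year),
                        drug_id = by_drug$drug_id,
                        n = as.integer(by_drug$Freq), stringsAsFactors = FALSE)
  by_class <- as.data.frame(table(year = year, drug_class = prescriptions$drug_class),
                            stringsAsFactors = FALSE)
  by_class <- by_class[by_class$Freq > 0L, , drop = FALSE]
  by_class <- data.frame(year = as.integer(by_class$year),
                         drug_class = by_class$drug_class,
                         n = as.integer(by_class$Freq), stringsAsFactors = FALSE)
  ord <- order(by_drug$year, by_drug$drug_id)
  by_drug <- by_drug[ord, , drop = FALSE]; rownames(by_drug) <- NULL
  ord <- order(by_class$year, by_class$drug_class)
  by_class <- by_class[ord, , drop = FALSE]; rownames(by_class) <- NULL
  list(by_drug = by_drug, by_class = by_class)
}

#' Phenotype a whole cohort
#'
#' Runs the full per-patient algorithm — MDD classification, episode
#' construction, switch detection, TRD classification, adherence proxy,
#' combination/augmentation flags and record density — over the union of
#' patients in the clinical and prescription tables (plus any extra ids in
#' `patient_ids`, who are classified from their empty record sets).
#'
#' @param clinical cohort clinical events ([read_clinical_table] layout).
#' @param prescriptions cohort prescription events
#'   ([read_prescription_table] layout).
#' @param params a [phenotype_params].
#' @param patient_ids optional character vector forcing the output to cover
#'   these patients (e.g. all cohort members, including those with no
#'   records).
#' @return data.frame, one row per patient: `patient_id`, `mdd_status`,
#'   `treated`, `trd_status`, `n_switches`,
#'   `adequate_interval_proportion`, `combination_flag`,
#'   `augmentation_flag`, `n_clinical_records`, `n_prescription_records`,
#'   `n_clinical_dates`, `n_prescription_dates`, `records_per_year`.
#' @export
phenotype_cohort <- function(clinical, prescriptions,
                             params = phenotype_params(),
                             patient_ids = NULL) {
  ids <- sort(unique(c(clinical$patient_id, prescriptions$patient_id,
                       as.character(patient_ids))))
  ev_split <- split(seq_len(nrow(clinical)), clinical$patient_id)
  rx_split <- split(seq_len(nrow(prescriptions)), prescriptions$patient_id)
  rows <- lapply(ids, function(id) {
    ev <- clinical[ev_split[[id]] %||% integer(), , drop = FALSE]
    rx <- prescriptions[rx_split[[id]] %||% integer(), , drop = FALSE]
    mdd <- classify_mdd(ev, params)
    treated <- any(rx$drug_class == "ANTIDEPRESSANT")
    eps <- build_drug_episodes(rx, params)
    sw <- detect_switches(eps, params)
    trd <- classify_trd(mdd, treated, nrow(sw))
    flags <- detect_combination_augmentation(rx, params)
    dens <- record_density(ev, rx)
    data.frame(
      patient_id = id,
      mdd_status = mdd,
      treated = treated,
      trd_status = trd,
      n_switches = nrow(sw),
      adequate_interval_proportion = adequate_interval_proportion(rx, params),
      combination_flag = flags$combination,
      augmentation_flag = flags$augmentation,
      n_clinical_records = dens$n_clinical_records,
      n_prescription_records = dens$n_prescription_records,
      n_clinical_dates = dens$n_clinical_dates,
      n_prescription_dates = dens$n_prescription_dates,
      records_per_year = dens$records_per_year,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      patient_id = character(), mdd_status = character(), treated = logical(),
      trd_status = character(), n_switches = integer(),
      adequate_interval_proportion = numeric(), combination_flag = logical(),
      augmentation_flag = logical(), n_clinical_records = integer(),
      n_prescription_records = integer(), n_clinical_dates = integer(),
      n_prescription_dates = integer(), records_per_year = numeric(),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
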