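#' @importFrom utils read.csv write.csv
NULL

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "tnmbn")
  if (!nzchar(p)) {
    # during development (package loaded from source tree)
    p <- file.path("inst", "extdata", file)
  }
  p
}

read_extdata_json <- function(file) {
  jsonlite::read_json(extdata_path(file), simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

# cached package data
.tnmbn_cache <- new.env(parent = emptyenv())

cached_json <- function(file) {
  if (is.null(.tnmbn_cache[[file]])) .tnmbn_cache[[file]] <- read_extdata_json(file)
  .tnmbn_cache[[file]]
}

#' Stage group labels
#'
#' The seven clinical stage groups for NSCLC used throughout the package,
#' in increasing order of disease extent. `UNKNOWN` marks descriptor
#' combinations that cannot yield a stage (e.g. TX/NX with M0); it is not
#' part of the network state space.
#' @return Character vector of stage labels.
#' @export
stage_levels <- function() c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV")

#' TNM descriptor vocabulary per edition
#'
#' Clinical T/N/M tokens legal in each TNM edition. Editions 5 and 6 share
#' one vocabulary; the 7th edition subdivides T1/T2 by tumor size and M1 by
#' metastasis site.
#'
#' @param edition `"5"`, `"6"` or `"7"` (numbers accepted).
#' @return List with components `t`, `n`, `m`.
#' @export
tnm_vocabulary <- function(edition) {
  edition <- check_edition(edition)
  if (edition == "7") {
    list(t = c("TX", "T0", "T1", "T1a", "T1b", "T2", "T2a", "T2b", "T3", "T4"),
         n = c("NX", "N0", "N1", "N2", "N3"),
         m = c("MX", "M0", "M1a", "M1b"))
  } else {
    list(t = c("TX", "T0", "T1", "T2", "T3", "T4"),
         n = c("NX", "N0", "N1", "N2", "N3"),
         m = c("MX", "M0", "M1"))
  }
}

check_edition <- function(edition) {
  ed <- as.character(edition)
  if (any(!ed %in% c("5", "6", "7"))) {
    stop("TNM edition must be one of 5, 6, 7 (got: ",
         paste(unique(ed[!ed %in% c("5", "6", "7")]), collapse = ", "), ")",
         call. = FALSE)
  }
  ed
}

#' Default incidence-year to TNM-edition mapping
#'
#' Read from the versioned configuration file shipped with the package:
#' 1999-2002 used the 5th edition, 2003-2009 the 6th, 2010-2016 the 7th.
#' @return Data frame with columns `from`, `to`, `edition`.
#' @export
default_edition_mapping <- function() {
  per <- cached_json("edition_years.json")$periods
  data.frame(from = vapply(per, function(p) as.integer(p$from), integer(1)),
             to = vapply(per, function(p) as.integer(p$to), integer(1)),
             edition = vapply(per, function(p) as.character(p$edition), character(1)),
             stringsAsFactors = FALSE)
}

#' TNM edition in use for an incidence year
#'
#' @param incidence_year Integer vector of calendar years.
#' @param mapping Data frame with columns `from`, `to`, `edition`
#'   (inclusive year ranges); defaults to [default_edition_mapping()].
#' @return Character vector of editions (`"5"`, `"6"`, `"7"`).
#' @export
assign_edition <- function(incidence_year, mapping = default_edition_mapping()) {
  year <- as.integer(incidence_year)
  out <- rep(NA_character_, length(year))
  for (i in seq_len(nrow(mapping))) {
    hit <- !is.na(year) & year >= mapping$from[i] & year <= mapping$to[i]
    out[hit] <- mapping$edition[i]
  }
  if (anyNA(out)) {
    stop("incidence year(s) outside the edition mapping: ",
         paste(unique(year[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Default survival category boundaries (months)
#'
#' Month cut-points delimiting the five survival categories
#' 0-<3, 3-<6, 6-<12, 12-<24 and >=24 months since diagnosis.
#' @return Numeric vector of four cut-points; the last must be 24.
#' @export
default_survival_boundaries <- function() c(3, 6, 12, 24)

#' Survival category labels for a set of boundaries
#' @param boundaries Ordered month cut-points (four values, last = 24 by
#'   default convention).
#' @return Character vector of five labels.
#' @export
survival_categories <- function(boundaries = default_survival_boundaries()) {
  lo <- c(0, boundaries)
  c(sprintf("%g-<%gmo", lo[-length(lo)], boundaries),
    sprintf(">=%gmo", boundaries[length(boundaries)]))
}

DAYS_PER_MONTH <- 30.44

#' Discretize follow-up into survival categories
#'
#' Patients who died are assigned the category containing their survival
#' time (months = days / 30.44). Patients alive with at least 24 months of
#' follow-up fall in the top category; patients alive with shorter
#' follow-up are right-censored below the top boundary and get `NA`
#' (missing survival category).
#'
#' @param follow_up_days Non-negative integer vector, days from diagnosis
#'   to death or last follow-up.
#' @param vital_status Character vector, `"alive"` or `"dead"`.
#' @param boundaries Month cut-points, see [default_survival_boundaries()].
#' @param days_per_month Calendar convention, default 30.44.
#' @return Character vector of category labels, `NA` where censored.
#' @export
discretize_survival <- function(follow_up_days, vital_status,
                                boundaries = default_survival_boundaries(),
                                days_per_month = DAYS_PER_MONTH) {
  days <- as.numeric(follow_up_days)
  if (any(is.na(days)) || any(days < 0)) {
    stop("follow_up_days must be non-negative", call. = FALSE)
  }
  status <- as.character(vital_status)
  if (any(!status %in% c("alive", "dead"))) {
    stop("vital_status must be 'alive' or 'dead'", call. = FALSE)
  }
  if (length(status) != length(days)) stop("length mismatch", call. = FALSE)
  labels <- survival_categories(boundaries)
  top_days <- ceiling(boundaries[length(boundaries)] * days_per_month)
  months <- days / days_per_month
  idx <- findInterval(months, c(0, boundaries))
  out <- labels[pmin(idx, length(labels))]
  censored <- status == "alive" & days < top_days
  out[status == "alive" & !censored] <- labels[length(labels)]
  out[censored] <- NA_character_
  out
}

# ---------------------------------------------------------------------------
# Stage grouping

grouping_table <- function(edition) {
  tab <- cached_json("stage_grouping.json")
  if (check_edition(edition) == "7") tab$edition7 else tab$edition6
}

definite_tokens <- function(edition) {
  if (check_edition(edition) == "7") {
    list(t = c("T1a", "T1b", "T2a", "T2b", "T3", "T4"),
         n = c("N0", "N1", "N2", "N3"),
         m = c("M0", "M1a", "M1b"))
  } else {
    list(t = c("T1", "T2", "T3", "T4"),
         n = c("N0", "N1", "N2", "N3"),
         m = c("M0", "M1"))
  }
}

metastatic_tokens <- c("M1", "M1a", "M1b")

expand_token <- function(token, which, edition) {
  def <- definite_tokens(edition)[[which]]
  if (token %in% def) return(token)
  switch(which,
         t = if (token == "TX") def
             else if (edition == "7" && token == "T1") c("T1a", "T1b")
             else if (edition == "7" && token == "T2") c("T2a", "T2b")
             else character(0),       # T0: not stage-groupable here
         n = if (token == "NX") def else character(0),
         m = if (token == "MX") def else character(0))
}

#' Candidate stage groups for a descriptor triple
#'
#' Expands unassessable (TX/NX/MX) and coarse (bare T1/T2 in the 7th
#' edition) tokens into their definite candidates and returns every stage
#' group reachable from the resulting combinations. Any metastatic M token
#' short-circuits to stage IV regardless of T and N.
#'
#' @param t,n,m Single descriptor tokens.
#' @param edition TNM edition of the tokens.
#' @return Character vector of stage groups (possibly empty when no
#'   combination is stage-groupable, e.g. T0).
#' @export
stage_candidates <- function(t, n, m, edition) {
  edition <- check_edition(edition)
  voc <- tnm_vocabulary(edition)
  if (!t %in% voc$t) stop(sprintf("'%s' is not a valid T token for edition %s", t, edition), call. = FALSE)
  if (!n %in% voc$n) stop(sprintf("'%s' is not a valid N token for edition %s", n, edition), call. = FALSE)
  if (!m %in% voc$m) stop(sprintf("'%s' is not a valid M token for edition %s", m, edition), call. = FALSE)
  ms <- expand_token(m, "m", edition)
  out <- character(0)
  if (any(ms %in% metastatic_tokens) || m %in% metastatic_tokens) out <- "IV"
  if (m %in% metastatic_tokens) return(out)
  if (!"M0" %in% ms) return(out)
  tab <- grouping_table(edition)
  ts <- expand_token(t, "t", edition)
  ns <- expand_token(n, "n", edition)
  for (tt in ts) for (nn in ns) out <- c(out, tab[[tt]][[nn]])
  stages <- stage_levels()
  stages[stages %in% out]
}

#' Stage group of a descriptor triple
#'
#' Deterministic lookup in the edition's encoded grouping table. A
#' metastatic M (M1/M1a/M1b) always yields stage IV. Triples whose
#' candidate expansion is not a single stage (e.g. TX/NX with M0) return
#' `"UNKNOWN"`.
#'
#' @param t,n,m Character vectors of descriptor tokens (recycled to a
#'   common length).
#' @param edition Edition vector (`"5"`, `"6"`, `"7"`); editions 5 and 6
#'   share one grouping table.
#' @return Character vector of stage groups.
#' @export
stage_group <- function(t, n, m, edition) {
  nmax <- max(length(t), length(n), length(m), length(edition))
  t <- rep_len(as.character(t), nmax)
  n <- rep_len(as.character(n), nmax)
  m <- rep_len(as.character(m), nmax)
  edition <- rep_len(check_edition(edition), nmax)
  out <- rep(NA_character_, nmax)
  for (ed_tab in c("6", "7")) {
    sel <- if (ed_tab == "7") edition == "7" else edition != "7"
    if (!any(sel)) next
    voc <- tnm_vocabulary(ed_tab)
    bad <- sel & !(t %in% voc$t & n %in% voc$n & m %in% voc$m)
    if (any(bad)) {
      i <- which(bad)[1]
      # re-derive the precise message through the scalar path
      stage_candidates(t[i], n[i], m[i], edition[i])
    }
    # fast vectorized path: metastatic M dominates; definite T/N/M0 triples
    # resolve through a flat lookup of the edition's grouping table
    meta <- sel & m %in% metastatic_tokens
    out[meta] <- "IV"
    def <- definite_tokens(ed_tab)
    tab <- grouping_table(ed_tab)
    flat <- unlist(tab)   # names like "T1.N0"
    plain <- sel & !meta & m == "M0" & t %in% def$t & n %in% def$n
    out[plain] <- unname(flat[paste(t[plain], n[plain], sep = ".")])
  }
  # slow path for TX/T0/NX/MX and coarse 7th-edition tokens
  rest <- which(is.na(out))
  for (i in rest) {
    cand <- stage_candidates(t[i], n[i], m[i], edition[i])
    out[i] <- if (length(cand) == 1L) cand else "UNKNOWN"
  }
  out
}

# ---------------------------------------------------------------------------
# Rule-based 7th -> 6th edition reclassification

match_condition <- function(when, multifocal, sulcus_superior) {
  if (is.null(when)) return(TRUE)
  ok <- TRUE
  for (fieldname in names(when)) {
    value <- switch(fieldname, multifocal = multifocal,
                    sulcus_superior = sulcus_superior,
                    stop("unknown rule condition field: ", fieldname, call. = FALSE))
    want <- when[[fieldname]]
    ok <- ok && if (identical(want, "missing")) is.na(value) else isTRUE(value == want)
  }
  ok
}

reclassify_one_7to6 <- function(t, n, m, multifocal = NA, tumor_size_mm = NA,
                                sulcus_superior = NA) {
  rules <- cached_json("reclass_rules_7to6.json")
  voc <- tnm_vocabulary("7")
  if (!t %in% voc$t || !n %in% voc$n || !m %in% voc$m) {
    stop(sprintf("(%s, %s, %s) is not a valid 7th-edition descriptor triple", t, n, m),
         call. = FALSE)
  }
  t_range <- NULL
  m_widen <- FALSE
  for (rule in rules$t_rules) {
    if (rule$t7 == t && match_condition(rule$when, multifocal, sulcus_superior)) {
      t_range <- as.character(unlist(rule$t6))
      m_widen <- isTRUE(rule$m_widen)
      break
    }
  }
  if (is.null(t_range)) {
    # bare T1/T2 without a matching refinement rule cannot occur with the
    # shipped rule table, but keep a defensive fallback
    t_range <- t
  }
  m_range <- as.character(unlist(rules$m_rules[[m]]))
  if (m_widen && identical(m_range, "M0")) m_range <- c("M0", "M1")
  stage_range <- character(0)
  for (tt in t_range) for (mm in m_range) {
    stage_range <- c(stage_range, stage_candidates(tt, n, mm, "6"))
  }
  stages <- c(stage_levels(), "UNKNOWN")
  stage_range <- stages[stages %in% stage_range]
  if (!length(stage_range)) stage_range <- "UNKNOWN"
  list(t_range = t_range, n = n, m_range = m_range, stage_range = stage_range,
       definitive = length(stage_range) == 1L && stage_range != "UNKNOWN")
}

#' Rule-based reclassification of 7th-edition records to the 6th edition
#'
#' Applies the declarative descriptor mapping rules derived from the AJCC
#' 6th-to-7th edition changes, inverted. The N descriptor always maps
#' identically. T and M may map to candidate ranges: a 7th-edition T3 with
#' unknown invasion status maps to \{T2, T3\}; a multifocal T4 (nodule in a
#' different ipsilateral lobe) makes both the 6th-edition T and M
#' undeterminable. Missing extra variables (multifocality, tumor size,
#' superior-sulcus involvement) widen ranges instead of erroring. The stage
#' range is the set of stage groups reachable from the Cartesian product of
#' descriptor candidates (metastatic M short-circuits to stage IV).
#'
#' @param records Data frame with columns `t`, `n`, `m` (7th-edition
#'   tokens), `edition`, and optionally `multifocal`, `tumor_size_mm`,
#'   `sulcus_superior`.
#' @return Data frame with one row per input record: `t_range`, `n`,
#'   `m_range`, `stage_range` (`|`-joined candidate sets), `stage` (the
#'   singleton stage, `NA` when ambiguous) and `definitive`.
#' @export
rule_reclassify_7to6 <- function(records) {
  if (!all(c("t", "n", "m") %in% names(records))) {
    stop("records must have columns t, n, m", call. = FALSE)
  }
  if (!is.null(records$edition) && any(as.character(records$edition) != "7")) {
    stop("rule_reclassify_7to6 requires 7th-edition records", call. = FALSE)
  }
  nr <- nrow(records)
  get_opt <- function(col, default = NA) {
    if (is.null(records[[col]])) rep(default, nr) else records[[col]]
  }
  multifocal <- get_opt("multifocal")
  size <- get_opt("tumor_size_mm")
  sulcus <- get_opt("sulcus_superior")
  rows <- lapply(seq_len(nr), function(i) {
    r <- reclassify_one_7to6(as.character(records$t[i]), as.character(records$n[i]),
                             as.character(records$m[i]),
                             multifocal[i], size[i], sulcus[i])
    data.frame(t_range = paste(r$t_range, collapse = "|"),
               n = r$n,
               m_range = paste(r$m_range, collapse = "|"),
               stage_range = paste(r$stage_range, collapse = "|"),
               stage = if (r$definitive) r$stage_range else NA_character_,
               definitive = r$definitive,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Registry CSV I/O

REGISTRY_COLUMNS <- c("incidence_year", "ct", "cn", "cm", "edition",
                      "follow_up_days", "vital_status", "multifocal",
                      "tumor_size_mm", "sulcus_superior")

#' Read a registry-style CSV of staged patient records
#'
#' Expected header columns: `incidence_year`, `ct`, `cn`, `cm`, `edition`
#' (optional; derived from the incidence year when absent), `follow_up_days`,
#' `vital_status`, and optionally `multifocal`, `tumor_size_mm`,
#' `sulcus_superior`. Empty strings are missing values. Stage group and the
#' discretized survival category are computed on read.
#'
#' @param path CSV file path.
#' @param mapping Edition-year mapping, see [assign_edition()].
#' @param boundaries Survival category boundaries in months.
#' @return Data frame with columns `incidence_year`, `edition`, `t`, `n`,
#'   `m`, `stage`, `follow_up_days`, `vital_status`, `survival`,
#'   `multifocal`, `tumor_size_mm`, `sulcus_superior`.
#' @export
read_registry <- function(path, mapping = default_edition_mapping(),
                          boundaries = default_survival_boundaries()) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("incidence_year", "ct", "cn", "cm", "follow_up_days", "vital_status")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("registry CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  edition <- if (!is.null(raw$edition) && !all(is.na(raw$edition) | raw$edition == "")) {
    check_edition(raw$edition)
  } else {
    assign_edition(raw$incidence_year, mapping)
  }
  opt_lgl <- function(col) {
    if (is.null(raw[[col]])) return(rep(NA, nrow(raw)))
    v <- raw[[col]]
    if (is.character(v)) v[v == ""] <- NA
    as.logical(v)
  }
  opt_num <- function(col) {
    if (is.null(raw[[col]])) return(rep(NA_real_, nrow(raw)))
    v <- raw[[col]]
    if (is.character(v)) v[v == ""] <- NA
    as.numeric(v)
  }
  out <- data.frame(
    incidence_year = as.integer(raw$incidence_year),
    edition = edition,
    t = as.character(raw$ct),
    n = as.character(raw$cn),
    m = as.character(raw$cm),
    follow_up_days = as.integer(raw$follow_up_days),
    vital_status = as.character(raw$vital_status),
    multifocal = opt_lgl("multifocal"),
    tumor_size_mm = opt_num("tumor_size_mm"),
    sulcus_superior = opt_lgl("sulcus_superior"),
    stringsAsFactors = FALSE
  )
  out$stage <- stage_group(out$t, out$n, out$m, out$edition)
  out$survival <- discretize_survival(out$follow_up_days, out$vital_status, boundaries)
  out[, c("incidence_year", "edition", "t", "n", "m", "stage",
          "follow_up_days", "vital_status", "survival",
          "multifocal", "tumor_size_mm", "sulcus_superior")]
}

#' Write patient records to the registry CSV dialect
#'
#' Inverse of [read_registry()]: UTF-8, comma separator, header required,
#' empty string for missing values.
#'
#' @param records Data frame as returned by [read_registry()] or
#'   [simulate_registry()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  out <- data.frame(
    incidence_year = records$incidence_year,
    ct = records$t,
    cn = records$n,
    cm = records$m,
    edition = records$edition,
    follow_up_days = records$follow_up_days,
    vital_status = records$vital_status,
    multifocal = records$multifocal,
    tumor_size_mm = records$tumor_size_mm,
    sulcus_superior = records$sulcus_superior,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
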