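# Red List category severity order (most to least severe)
IUCN_LEVELS <- c("CR", "EN", "VU", "NT", "LC")

# decline sub-criteria (condition b): i EOO, ii AOO, iii habitat, iv
# locations/subpopulations, v mature individuals
DECLINE_FLAGS <- c("i", "ii", "iii", "iv", "v")
# fluctuation sub-criteria (condition c): i EOO, ii AOO, iii
# locations/subpopulations, iv mature individuals
FLUCT_FLAGS <- c("i", "ii", "iii", "iv")

severity <- function(cat) match(cat, IUCN_LEVELS)
most_severe <- function(cats) {
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0) return(NA_character_)
  IUCN_LEVELS[min(severity(cats))]
}

#' Assemble an assessment input
#'
#' The quantitative facts the criterion engine consumes. Decline and
#' fluctuation flags are caller-supplied determinations (see
#' [flag_extreme_fluctuation()] for an optional data-driven helper).
#'
#' @param eoo_km2,aoo_km2 range metrics (either may be NA)
#' @param n_locations number of threat-defined locations
#' @param severely_fragmented logical
#' @param continuing_decline character subset of `c("i","ii","iii","iv","v")`
#' @param extreme_fluctuations character subset of `c("i","ii","iii","iv")`
#' @param n_mature count of mature individuals (NA to skip criterion D)
#' @param extinction_probability optional list with `p`, `years` (and
#'   optionally `generations`) from a PVA, for criterion E
#' @return an `assessment_input` list
#' @export
assessment_input <- function(eoo_km2 = NA, aoo_km2 = NA, n_locations = NA,
                             severely_fragmented = FALSE,
                             continuing_decline = character(0),
                             extreme_fluctuations = character(0),
                             n_mature = NA,
                             extinction_probability = NULL) {
  if (length(setdiff(continuing_decline, DECLINE_FLAGS)) > 0) {
    stop_endemica("invalid continuing-decline flag",
                  "endemica_validation_error")
  }
  if (length(setdiff(extreme_fluctuations, FLUCT_FLAGS)) > 0) {
    stop_endemica("invalid extreme-fluctuation flag",
                  "endemica_validation_error")
  }
  if ((!is.na(eoo_km2) && eoo_km2 < 0) || (!is.na(aoo_km2) && aoo_km2 < 0)) {
    stop_endemica("areas must be non-negative", "endemica_validation_error")
  }
  structure(list(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2,
                 n_locations = n_locations,
                 severely_fragmented = isTRUE(severely_fragmented),
                 continuing_decline = sort(match(continuing_decline,
                                                 DECLINE_FLAGS)),
                 extreme_fluctuations = sort(match(extreme_fluctuations,
                                                   FLUCT_FLAGS)),
                 n_mature = n_mature,
                 extinction_probability = extinction_probability),
            class = "assessment_input")
}

# shared machinery for B1 (EOO) and B2 (AOO)
assess_b_sub <- function(area, thresholds, input, prefix) {
  loc_limits <- c(CR = 1, EN = 5, VU = 10)
  has_decline <- length(input$continuing_decline) > 0
  has_fluct <- length(input$extreme_fluctuations) > 0
  category <- NA_character_
  for (lev in c("CR", "EN", "VU")) {
    if (!(area < thresholds[lev])) next
    cond_a <- input$severely_fragmented ||
      (!is.na(input$n_locations) && input$n_locations <= loc_limits[lev])
    if (cond_a + has_decline + has_fluct >= 2) { category <- lev; break }
  }
  # near-threshold heuristic: within 10% above the VU area threshold with
  # the condition count still satisfied -> NT
  if (is.na(category) && area < thresholds["VU"] * 1.1) {
    cond_a <- input$severely_fragmented ||
      (!is.na(input$n_locations) && input$n_locations <= loc_limits["VU"])
    if (cond_a + has_decline + has_fluct >= 2) category <- "NT"
  }
  code <- NA_character_
  if (!is.na(category) && category %in% c("CR", "EN", "VU")) {
    lev <- category
    cond_a <- input$severely_fragmented ||
      (!is.na(input$n_locations) && input$n_locations <= loc_limits[lev])
    parts <- prefix
    if (cond_a) parts <- paste0(parts, "a")
    if (has_decline) {
      parts <- paste0(parts, "b(",
                      paste(DECLINE_FLAGS[input$continuing_decline],
                            collapse = ","), ")")
    }
    if (has_fluct) {
      parts <- paste0(parts, "c(",
                      paste(FLUCT_FLAGS[input$extreme_fluctuations],
                            collapse = ","), ")")
    }
    code <- parts
  }
  list(category = category, code = code)
}

#' Criterion B: restricted geographic range
#'
#' B1 applies EOO thresholds (< 100 / 5000 / 20000 km^2 for CR / EN / VU),
#' B2 applies AOO thresholds (< 10 / 500 / 2000 km^2). A qualifying area
#' additionally requires at least two of: (a) severe fragmentation or few
#' locations (<= 1 / 5 / 10), (b) continuing decline in any listed aspect,
#' (c) extreme fluctuations in any listed aspect. Thresholds are strict
#' ("less than"): an EOO of exactly 100 km^2 does not qualify for CR.
#' Criteria codes such as `B1ab(i,ii,iii,v)c(i,ii,iv)` list the conditions
#' and flags present.
#'
#' @param input an [assessment_input()]
#' @return list with `B1` and `B2`, each `category` + `code`, and the
#'   combined `category`
#' @export
assess_criterion_b <- function(input) {
  if (is.na(input$eoo_km2) && is.na(input$aoo_km2)) {
    stop_endemica("criterion B needs EOO or AOO", "endemica_validation_error")
  }
  b1 <- if (!is.na(input$eoo_km2)) {
    assess_b_sub(input$eoo_km2,
                 c(CR = 100, EN = 5000, VU = 20000), input, "B1")
  } else list(category = NA_character_, code = NA_character_)
  b2 <- if (!is.na(input$aoo_km2)) {
    assess_b_sub(input$aoo_km2,
                 c(CR = 10, EN = 500, VU = 2000), input, "B2")
  } else list(category = NA_character_, code = NA_character_)
  list(B1 = b1, B2 = b2,
       category = most_severe(c(b1$category, b2$category)))
}

#' Criterion D: very small population
#'
#' CR for fewer than 50 mature individuals, EN below 250, VU below 1000
#' (strict thresholds); within 10% above the VU threshold the NT heuristic
#' applies.
#'
#' @param n_mature count of mature individuals
#' @return category string or NA when not triggered
#' @export
assess_criterion_d <- function(n_mature) {
  stopifnot(n_mature >= 0)
  if (n_mature < 50) return("CR")
  if (n_mature < 250) return("EN")
  if (n_mature < 1000) return("VU")
  if (n_mature < 1100) return("NT")
  NA_character_
}

#' Criterion E: quantitative extinction risk
#'
#' CR when extinction probability reaches 0.5 within 10 years (or 3
#' generations), EN at 0.2 within 20 years (or 5 generations), VU at 0.1
#' within 100 years.
#'
#' @param p extinction probability in `[0, 1]`
#' @param years time frame of the estimate in years
#' @param generations optional time frame in generations
#' @return category string or NA when not triggered
#' @export
assess_criterion_e <- function(p, years, generations = NA) {
  stopifnot(p >= 0, p <= 1)
  within <- function(y_lim, g_lim = NA) {
    (!is.na(years) && years <= y_lim) ||
      (!is.na(generations) && !is.na(g_lim) && generations <= g_lim)
  }
  if (p >= 0.5 && within(10, 3)) return("CR")
  if (p >= 0.2 && within(20, 5)) return("EN")
  if (p >= 0.1 && within(100)) return("VU")
  NA_character_
}

#' Full Red List assessment
#'
#' Evaluates criterion B (B1/B2) and, where inputs are present, D and E;
#' the overall category is the most severe of the per-criterion categories
#' and all triggering codes are listed. Criteria A and C are out of scope
#' (they require trend-over-generation and subpopulation-structure inputs
#' not covered here).
#'
#' @param input an [assessment_input()]
#' @return an `assessment_result` list: `category`, `codes`, `criteria`
#'   (per-criterion breakdown)
#' @export
assess <- function(input) {
  stopifnot(inherits(input, "assessment_input"))
  criteria <- list()
  codes <- character(0)
  cats <- character(0)
  if (!is.na(input$eoo_km2) || !is.na(input$aoo_km2)) {
    b <- assess_criterion_b(input)
    criteria$B <- b
    cats <- c(cats, b$category)
    for (sub in list(b$B1, b$B2)) {
      if (!is.na(sub$code)) codes <- c(codes, sub$code)
    }
  }
  if (!is.na(input$n_mature)) {
    d <- assess_criterion_d(input$n_mature)
    criteria$D <- d
    cats <- c(cats, d)
    if (!is.na(d) && d %in% c("CR", "EN", "VU")) codes <- c(codes, "D")
  }
  if (!is.null(input$extinction_probability)) {
    ep <- input$extinction_probability
    e <- assess_criterion_e(ep$p, ep$years,
                            if (is.null(ep$generations)) NA else
                              ep$generations)
    criteria$E <- e
    cats <- c(cats, e)
    if (!is.na(e)) codes <- c(codes, "E")
  }
  if (length(criteria) == 0) {
    stop_endemica("no criterion evaluable from the supplied facts",
                  "endemica_validation_error")
  }
  overall <- most_severe(cats)
  if (is.na(overall)) overall <- "LC"
  structure(list(category = overall, codes = codes, criteria = criteria),
            class = "assessment_result")
}

#' Parse a criterion-B code string
#'
#' Inverse of the code assembly in [assess_criterion_b()]: splits a string
#' like `"B1ab(i,ii,iii,v)c(i,ii,iv)"` into its sub-criterion and flag sets.
#'
#' @param code code string
#' @return list with `criterion` ("B1"/"B2"), `cond_a` logical,
#'   `decline` and `fluctuation` character flag vectors
#' @export
parse_b_code <- function(code) {
  m <- regmatches(code, regexec("^(B[12])(a?)(b\\(([ivx,]+)\\))?(c\\(([ivx,]+)\\))?$",
                                code))[[1]]
  if (length(m) == 0) {
    stop_endemica("unparseable criterion code", "endemica_format_error")
  }
  list(criterion = m[2], cond_a = m[3] == "a",
       decline = if (m[5] != "") strsplit(m[5], ",")[[1]] else character(0),
       fluctuation = if (m[7] != "") strsplit(m[7], ",")[[1]] else
         character(0))
}

#' Data-driven extreme-fluctuation helper
#'
#' IUCN guidance reads "extreme fluctuations" as variation of about one
#' order of magnitude. This helper flags a census series whose max/min
#' ratio reaches `ratio_threshold` (default 10). Note that assessments in
#' practice sometimes assert extreme fluctuations at much smaller ratios;
#' the criterion engine therefore accepts the flag as a caller-supplied
#' fact, and this helper merely documents what the data alone support.
#'
#' @param totals census series of mature individuals
#' @param ratio_threshold max/min ratio regarded as extreme (default 10)
#' @return list with `extreme` logical and the observed `ratio`
#' @export
flag_extreme_fluctuation <- function(totals, ratio_threshold = 10) {
  stopifnot(length(totals) >= 2)
  if (min(totals) == 0) return(list(extreme = TRUE, ratio = Inf))
  ratio <- max(totals) / min(totals)
  list(extreme = ratio >= ratio_threshold, ratio = ratio)
}
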