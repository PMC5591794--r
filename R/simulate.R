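#' @include profile.R reporting.R
NULL

#' Configuration for synthetic cohort simulation
#'
#' Per-site obstruction-degree probabilities and, for sites that admit
#' configurations, per-configuration probabilities. The default degree
#' distribution `(p0, p1, p2) = (0.5, 0.3, 0.2)` at every site gives an
#' expected severity index of `7 * (0.3 + 2 * 0.2) = 4.9`; configurations
#' default to uniform over each site's admissible set. Sites are simulated
#' independently (no joint prevalence structure is modelled).
#'
#' @param nPatients Positive integer number of profiles.
#' @param seed Integer RNG seed; identical configurations yield identical
#'   cohorts.
#' @param degreeProbs Named list, structure code -> numeric triple
#'   `(p0, p1, p2)`; unlisted sites use `default`.
#' @param configProbs Named list, structure code -> named probability vector
#'   over the site's admissible configurations; defaults to uniform.
#' @param default Numeric triple used for sites absent from `degreeProbs`.
#' @return A list of class `SimulationConfig`.
#' @examples
#' simulationConfig(100, seed = 1)
#' @export
simulationConfig <- function(nPatients, seed = 1L,
                             degreeProbs = list(),
                             configProbs = list(),
                             default = c(0.5, 0.3, 0.2)) {
  if (!is.numeric(nPatients) || length(nPatients) != 1L ||
      nPatients < 1 || nPatients != as.integer(nPatients)) {
    stop("nPatients must be a positive integer", call. = FALSE)
  }
  dp <- lapply(stats::setNames(.STRUCTURES$code, .STRUCTURES$code),
               function(code) {
    p <- if (code %in% names(degreeProbs)) degreeProbs[[code]] else default
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("degree probabilities for ", code,
           " must be a nonnegative triple summing to 1", call. = FALSE)
    }
    p
  })
  cp <- lapply(stats::setNames(.STRUCTURES$code, .STRUCTURES$code),
               function(code) {
    allowed <- .ALLOWED_CONFIGS[[code]]
    if (!length(allowed)) return(NULL)
    p <- if (code %in% names(configProbs)) configProbs[[code]]
         else stats::setNames(rep(1 / length(allowed), length(allowed)),
                              allowed)
    if (!setequal(names(p), allowed) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop("configuration probabilities for ", code,
           " must cover exactly {", paste(allowed, collapse = ", "),
           "} and sum to 1", call. = FALSE)
    }
    p[allowed]
  })
  structure(list(nPatients = as.integer(nPatients), seed = as.integer(seed),
                 degreeProbs = dp, configProbs = cp),
            class = "SimulationConfig")
}

#' Simulate a synthetic uDISE cohort
#'
#' Draws `nPatients` profiles: per site, a degree from the configured
#' triple; whenever the degree is >= 1 at a site with configurations, a
#' configuration from the site's probability vector. Degree-0 findings
#' carry no configuration (canonical form). The same configuration (seed
#' included) always reproduces the same cohort.
#'
#' @param config A [simulationConfig()] object, or a bare patient count
#'   (the default configuration is then used with `seed`).
#' @param seed Seed used when `config` is a bare count.
#' @return A list of [UdiseProfile-class] objects.
#' @examples
#' cohort <- simulateCohort(simulationConfig(10, seed = 42))
#' cohortSummary(cohort)$severity$mean
#' @export
simulateCohort <- function(config, seed = 1L) {
  if (is.numeric(config)) config <- simulationConfig(config, seed = seed)
  if (!inherits(config, "SimulationConfig")) {
    stop("config must be a SimulationConfig or a patient count",
         call. = FALSE)
  }
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(config$seed)
  lapply(seq_len(config$nPatients), function(i) {
    udiseProfile(lapply(.STRUCTURES$code, function(code) {
      d <- sample(0:2, 1L, prob = config$degreeProbs[[code]])
      cfg <- NA_character_
      cpr <- config$configProbs[[code]]
      if (d >= 1L && !is.null(cpr)) {
        cfg <- sample(names(cpr), 1L, prob = cpr)
      }
      siteFinding(code, d, cfg)
    }))
  })
}

#' Worked score-string examples of the model
#'
#' The canonical worked examples: a completely normal examination, isolated
#' partial tonsillar obstruction, simple palatal snoring, a single-level
#' complete epiglottic collapse, and a multilevel tonsil + tongue-base
#' obstruction, each with its severity index.
#'
#' @return A data frame with columns `name`, `score` and `severity`.
#' @examples
#' workedExamples()
#' @export
workedExamples <- function() {
  data.frame(
    name = c("normal", "tonsillar", "palatal_snoring", "epiglottic",
             "multilevel"),
    score = c("N0V0Ts0O0Tb0E0L0",
              "N0V0Ts1LO0Tb0E0L0",
              "N0V1APTs0O0Tb0E0L0",
              "N0V0Ts0O0Tb0E2APL0",
              "N0V0Ts2LO0Tb2APE0L0"),
    severity = c(0L, 1L, 1L, 2L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Hand-curated reference grid fixture
#'
#' Loads the independently hand-encoded snapshot of the reference crosswalk
#' grid shipped under `extdata/reference-grid.csv`. It is deliberately not
#' derived from the rule base, so comparing it cell-by-cell against
#' [generateReferenceTable()] is a genuine cross-check of the rule
#' encoding.
#'
#' @return A data frame in the same shape as [generateReferenceTable()].
#' @export
referenceGridFixture <- function() {
  path <- system.file("extdata", "reference-grid.csv", package = "udise",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  df$configuration[df$configuration == ""] <- NA_character_
  df
}
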