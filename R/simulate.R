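# Synthetic ICSR generator. Spontaneous-report databases are not publicly
# redistributable, so validation runs on simulated cohorts that reproduce the
# statistical structure the analysis relies on: heavy-tailed per-drug
# marginal prevalences, block-structured co-prescription (therapy profiles),
# overdispersed per-report drug counts, demographic strata, and the noise the
# exclusion cascade has to handle (flagged duplicates, unmappable names).

#' Define a therapy profile
#'
#' A therapy profile is a block of drugs that tend to be co-prescribed (e.g.
#' a heart-failure regimen or an acute-infection regimen). When a report
#' activates the profile, each member drug is included independently with its
#' inclusion probability. Profiles are the planted communities that the
#' network clustering should recover.
#'
#' @param label profile name.
#' @param drugs character vector of member drug names.
#' @param inclusion per-drug inclusion probabilities (recycled if length 1).
#' @param activation probability that a report activates this profile.
#' @return a `therapy_profile` list.
#' @export
therapy_profile <- function(label, drugs, inclusion, activation) {
  inclusion <- rep_len(inclusion, length(drugs))
  stopifnot(length(drugs) >= 1, all(inclusion >= 0 & inclusion <= 1),
            activation >= 0, activation <= 1)
  structure(list(label = label, drugs = tolower(drugs),
                 inclusion = inclusion, activation = activation),
            class = "therapy_profile")
}

#' Simulation configuration
#'
#' Bundles everything [simulate_icsr()] needs. All random draws flow from the
#' single `seed` in a documented order (demographics, then per-report frailty,
#' then profile activations, inclusions and background drugs, then noise), so
#' a config is fully reproducible.
#'
#' @param n_reports number of reports to emit (including flagged duplicates).
#' @param drug_universe tibble with columns `drug`, `atc_code`: every name the
#'   generator may emit, with its ATC code (the map handed to the filters).
#' @param profiles list of [therapy_profile()] objects; members must belong to
#'   the universe. May be empty if `background_rate > 0`.
#' @param background_rate probability that any given universe drug is added to
#'   a report independently of the profiles (reporting noise; also the only
#'   source of cross-profile pairs when profiles are disjoint).
#' @param demographics list with elements `sex_probs` (named: female/male/
#'   unknown), `age_mean`, `age_sd`, `age_unknown`, `region_probs`,
#'   `reporter_probs`, `serious_prob`, `serious_unknown`, `death_prob`, and
#'   optional `death_prob_over65` (emulates the higher fatality of the older
#'   stratum; `NULL` keeps the marginal rate for everyone).
#' @param noise list with `duplicate_fraction` (share of reports that are
#'   flagged near-copies of another report) and `unknown_name_fraction`
#'   (per-entry chance the drug name is replaced by an unmappable token).
#' @param frailty_shape shape of the gamma (mean-1) per-report frailty that
#'   multiplies profile activation odds; smaller values give the heavier
#'   polypharmacy tail; `Inf` disables frailty.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_reports, drug_universe, profiles = list(),
                       background_rate = 0, demographics = default_demographics(),
                       noise = list(duplicate_fraction = 0,
                                    unknown_name_fraction = 0),
                       frailty_shape = Inf, seed = 1) {
  stopifnot(n_reports >= 1, nrow(drug_universe) >= 2,
            all(c("drug", "atc_code") %in% names(drug_universe)))
  drug_universe$drug <- tolower(drug_universe$drug)
  if (anyDuplicated(drug_universe$drug))
    stop("drug_universe has duplicated names")
  probs <- c(background_rate, noise$duplicate_fraction,
             noise$unknown_name_fraction,
             unlist(lapply(profiles, function(p) c(p$inclusion, p$activation))))
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  for (p in profiles) {
    if (!all(p$drugs %in% drug_universe$drug))
      stop("profile '", p$label, "' uses drugs outside the universe")
  }
  if (!length(profiles) && background_rate == 0)
    stop("need at least one profile or a positive background_rate")
  structure(list(n_reports = as.integer(n_reports),
                 drug_universe = tibble::as_tibble(drug_universe),
                 profiles = profiles, background_rate = background_rate,
                 demographics = demographics, noise = noise,
                 frailty_shape = frailty_shape, seed = as.integer(seed)),
            class = "sim_config")
}

#' Demographic distributions used when none are specified
#'
#' Roughly the composition of a large international spontaneous-report cohort
#' of a serious cutaneous reaction: predominantly female, mean age in the late
#' fifties, mostly European reports filed by physicians, a large majority of
#' serious outcomes and a fatality rate of a few percent.
#'
#' @return a demographics list (see [sim_config()]).
#' @export
default_demographics <- function() {
  list(
    sex_probs = c(female = 0.593, male = 0.385, unknown = 0.022),
    age_mean = 57.3, age_sd = 21.8, age_unknown = 0.086,
    region_probs = c(Europe = 0.598, Asia = 0.234, Africa = 0.010,
                     `North America` = 0.141, Oceania = 0.013,
                     `South America` = 0.004),
    reporter_probs = c(physician = 0.656, `other health professional` = 0.112,
                       `nonhealth professional` = 0.020, unknown = 0.212),
    serious_prob = 0.919, serious_unknown = 0.105,
    death_prob = 0.025, death_prob_over65 = NULL
  )
}

#' ATC mapping implied by a simulation config
#'
#' The universe's (drug, ATC) table, i.e. the mapping the exclusion filters
#' should be run with. Unknown-name tokens emitted by the noise model are by
#' construction absent from it.
#'
#' @param config a `sim_config`.
#' @return tibble with `drug`, `atc_code`.
#' @export
atc_table <- function(config) {
  config$drug_universe[, c("drug", "atc_code")]
}

#' Generate a synthetic ICSR cohort
#'
#' Draws `n_reports` reports under `config`: demographics are sampled
#' independently from the configured distributions; each report activates each
#' therapy profile independently (activation odds scaled by a per-report
#' gamma frailty), includes member drugs of active profiles with their
#' inclusion probabilities, and adds any universe drug with
#' `background_rate`; reports that end up with an empty drug set are redrawn
#' (up to 100 attempts, then one uniformly chosen profile — or universe drug,
#' if there are no profiles — is forced in). Noise is applied last: a
#' configured fraction of reports are replaced by flagged near-copies of
#' other reports, and a configured fraction of drug entries have their name
#' replaced by an unmappable token.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `entries` (report_id, drug, role), `meta` (per-report
#'   demographics + `duplicate_flag`), and `truth`: `drug_labels` (planted
#'   profile per profile drug), `report_profiles` (logical matrix reports x
#'   profiles), `unknown_map` (report_id, token, drug) for the renamed
#'   entries, and `duplicate_of` (report_id of the copied original).
#' @export
simulate_icsr <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  with_local_seed(seed, simulate_icsr_impl(config))
}

simulate_icsr_impl <- function(config) {
  dem <- config$demographics
  noise <- config$noise
  n_dup <- floor(config$n_reports * (noise$duplicate_fraction %||% 0))
  n <- config$n_reports - n_dup
  universe <- config$drug_universe$drug
  U <- length(universe)
  P <- length(config$profiles)

  ## 1. demographics (drawn first, one vector per field)
  sex <- sample(names(dem$sex_probs), n, TRUE, dem$sex_probs)
  age <- pmin(pmax(rnorm(n, dem$age_mean, dem$age_sd), 0), 100)
  age[runif(n) < dem$age_unknown] <- NA
  region <- sample(names(dem$region_probs), n, TRUE, dem$region_probs)
  reporter <- sample(names(dem$reporter_probs), n, TRUE, dem$reporter_probs)
  serious <- rbinom(n, 1, dem$serious_prob) == 1
  serious[runif(n) < (dem$serious_unknown %||% 0)] <- NA
  death_p <- rep(dem$death_prob, n)
  if (!is.null(dem$death_prob_over65))
    death_p[!is.na(age) & age >= 65] <- dem$death_prob_over65
  death <- rbinom(n, 1, death_p) == 1

  ## 2. per-report frailty
  frailty <- if (is.finite(config$frailty_shape))
    stats::rgamma(n, shape = config$frailty_shape,
                  rate = config$frailty_shape) else rep(1, n)

  ## 3. profile activation, inclusion, background (vectorized; empty reports
  ##    redrawn)
  draw_drugs <- function(idx) {
    m <- length(idx)
    has <- matrix(FALSE, m, U)
    active <- matrix(FALSE, m, max(P, 1))
    for (p in seq_len(P)) {
      prof <- config$profiles[[p]]
      act <- rbinom(m, 1, pmin(1, frailty[idx] * prof$activation)) == 1
      active[, p] <- act
      if (any(act)) {
        cols <- match(prof$drugs, universe)
        inc <- matrix(rbinom(sum(act) * length(cols), 1,
                             rep(prof$inclusion, each = sum(act))) == 1,
                      nrow = sum(act))
        has[idx_rows(act), cols] <- has[idx_rows(act), cols] | inc
      }
    }
    if (config$background_rate > 0)
      has <- has | matrix(rbinom(m * U, 1, config$background_rate) == 1, m, U)
    list(has = has, active = active)
  }
  idx_rows <- function(flags) which(flags)

  d <- draw_drugs(seq_len(n))
  has <- d$has
  active <- d$active
  for (attempt in seq_len(100)) {
    empty <- which(rowSums(has) == 0)
    if (!length(empty)) break
    rd <- draw_drugs(empty)
    has[empty, ] <- rd$has
    active[empty, ] <- rd$active
  }
  empty <- which(rowSums(has) == 0)
  if (length(empty)) {  # capped retries exhausted: force one profile/drug
    if (P > 0) {
      forced <- sample.int(P, length(empty), replace = TRUE)
      for (k in seq_along(empty)) {
        prof <- config$profiles[[forced[k]]]
        inc <- rbinom(length(prof$drugs), 1, prof$inclusion) == 1
        if (!any(inc)) inc[sample.int(length(inc), 1)] <- TRUE
        has[empty[k], match(prof$drugs, universe)] <- inc
        active[empty[k], forced[k]] <- TRUE
      }
    } else {
      has[cbind(empty, sample.int(U, length(empty), replace = TRUE))] <- TRUE
    }
  }

  ids <- sprintf("r%06d", seq_len(n))
  which_has <- which(has, arr.ind = TRUE)
  ord <- order(which_has[, 1], which_has[, 2])
  entries <- tibble::tibble(
    report_id = ids[which_has[ord, 1]],
    drug = universe[which_has[ord, 2]]
  )
  first <- !duplicated(entries$report_id)
  role <- sample(c("concomitant", "suspected", "interacting"),
                 nrow(entries), TRUE, c(0.80, 0.15, 0.05))
  role[first] <- "suspected"
  entries$role <- role

  meta <- tibble::tibble(report_id = ids, age_years = age, sex = sex,
                         region = region, reporter = reporter,
                         serious = serious, death = death,
                         duplicate_flag = FALSE)

  ## 4. noise: flagged duplicate near-copies, then unknown-name tokens
  duplicate_of <- tibble::tibble(report_id = character(),
                                 original = character())
  if (n_dup > 0) {
    src <- sample(ids, n_dup, replace = TRUE)
    dup_ids <- sprintf("d%06d", seq_len(n_dup))
    dup_entries <- entries[entries$report_id %in% src, ]
    dup_entries <- dplyr::left_join(
      tibble::tibble(original = src, report_id = dup_ids),
      dplyr::rename(dup_entries, original = "report_id"),
      by = "original", relationship = "many-to-many")
    dup_meta <- meta[match(src, meta$report_id), ]
    dup_meta$report_id <- dup_ids
    dup_meta$duplicate_flag <- TRUE
    entries <- dplyr::bind_rows(entries,
                                dup_entries[, c("report_id", "drug", "role")])
    meta <- dplyr::bind_rows(meta, dup_meta)
    duplicate_of <- tibble::tibble(report_id = dup_ids, original = src)
  }

  unknown_map <- tibble::tibble(report_id = character(), token = character(),
                                drug = character())
  uf <- noise$unknown_name_fraction %||% 0
  if (uf > 0) {
    hit <- which(runif(nrow(entries)) < uf)
    if (length(hit)) {
      tokens <- sprintf("unlabelled_%05d", seq_along(hit))
      unknown_map <- tibble::tibble(report_id = entries$report_id[hit],
                                    token = tokens, drug = entries$drug[hit])
      entries$drug[hit] <- tokens
    }
  }

  drug_labels <- tibble::tibble(
    drug = as.character(unlist(lapply(config$profiles, `[[`, "drugs"))),
    profile = rep(vapply(config$profiles, `[[`, "", "label"),
                  vapply(config$profiles, function(p) length(p$drugs), 1L))
  ) |> dplyr::distinct(.data$drug, .keep_all = TRUE)  # first profile wins

  list(entries = entries, meta = meta,
       truth = list(drug_labels = drug_labels,
                    report_profiles = if (P) {
                      dimnames(active) <- list(
                        ids, vapply(config$profiles, `[[`, "", "label"))
                      active
                    } else NULL,
                    unknown_map = unknown_map,
                    duplicate_of = duplicate_of))
}

#' Two disjoint planted profiles
#'
#' The benchmark configuration for planted-community recovery: two disjoint
#' blocks of `block_size` drugs, activated independently per report, plus a
#' pool of background-only drugs. With the defaults, within-block pairs are
#' strongly over-reported while cross-block pairs arise only through
#' co-activation and background noise, so both clustering methods should
#' recover the blocks exactly.
#'
#' @param n_reports cohort size.
#' @param inclusion member-drug inclusion probability.
#' @param background_rate background drug probability.
#' @param activation per-profile activation probability.
#' @param block_size drugs per profile.
#' @param n_background_drugs extra background-only drugs in the universe.
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
two_profile_config <- function(n_reports = 5000, inclusion = 0.8,
                               background_rate = 0.005, activation = 0.5,
                               block_size = 5, n_background_drugs = 10,
                               seed = 1) {
  cardio <- sprintf("cardio%02d", seq_len(block_size))
  antibio <- sprintf("antibio%02d", seq_len(block_size))
  bg <- sprintf("bgdrug%02d", seq_len(n_background_drugs))
  universe <- tibble::tibble(
    drug = c(cardio, antibio, bg),
    atc_code = c(sprintf("C01AA%02d", seq_len(block_size)),
                 sprintf("J01CA%02d", seq_len(block_size)),
                 sprintf("N02BE%02d", seq_len(n_background_drugs)))
  )
  sim_config(
    n_reports = n_reports, drug_universe = universe,
    profiles = list(
      therapy_profile("cardiovascular", cardio, inclusion, activation),
      therapy_profile("antibiotic", antibio, inclusion, activation)
    ),
    background_rate = background_rate, seed = seed
  )
}
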