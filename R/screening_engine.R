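# Multi-criteria screening: threshold rules per criterion, curated-verdict
# overrides, aggregation to candidate/excluded status, and the rendered
# summary matrix.

#' Screening criteria
#'
#' The seven primary criteria every site must be judged on (target-species
#' presence, geographic isolation, genetic isolation, genetic diversity,
#' size, topography, anopheline species richness) and the four secondary
#' considerations carried as curated or deferred flags (insecticide
#' susceptibility, Plasmodium prevalence, endangered species, travel
#' feasibility).
#'
#' @format character vectors of criterion names.
#' @export
PRIMARY_CRITERIA <- c("target_present", "geographic_isolation", "genetic_isolation",
                      "genetic_diversity", "size", "topography", "richness")

#' @rdname PRIMARY_CRITERIA
#' @export
SECONDARY_CRITERIA <- c("insecticide", "plasmodium", "endangered", "travel")
VERDICT_LEVELS <- c("pass", "fail", "missing", "deferred")
VERDICT_SYMBOLS <- c(pass = "✓", fail = "✗", missing = "‐",
                     deferred = "*")

#' Screening thresholds
#'
#' Numeric thresholds applied by the computed screening rules. The isolation
#' cutoffs are the stated ones: an island is geographically unacceptable
#' with a UNEP Isolation Index below 15 or a surrounding landmass proportion
#' above 1. The remaining thresholds are unstated in the source material and
#' are calibrated so the computed rules separate the worked examples of
#' included and excluded islands (e.g. the default 600 m relief minimum lies
#' between excluded Mfangano at 551 m and included Mayotte at 636 m); all
#' are exposed here.
#'
#' @param unep_min minimum UNEP Isolation Index (strict: fail when < this).
#' @param slmp_max maximum SLMP (strict: fail when > this).
#' @param area_min,area_max island area bounds, km^2 (inclusive).
#' @param relief_min minimum relief (elevation max - min), m (inclusive).
#' @param richness_max maximum anopheline species count (inclusive).
#' @param fst_isolation_min minimum island-mainland FST for genetic
#'   isolation (inclusive).
#' @param flight_range_km assumed maximal daily flight range of the target
#'   species, used to reason about minimum site extent.
#' @export
screening_config <- function(unep_min = 15, slmp_max = 1.0, area_min = 100,
                             area_max = 10000, relief_min = 600,
                             richness_max = 10, fst_isolation_min = 0.10,
                             flight_range_km = 10) {
  cfg <- list(unep_min = unep_min, slmp_max = slmp_max, area_min = area_min,
              area_max = area_max, relief_min = relief_min,
              richness_max = richness_max,
              fst_isolation_min = fst_isolation_min,
              flight_range_km = flight_range_km)
  if (any(vapply(cfg, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all thresholds must be positive numbers")
  }
  if (area_min >= area_max) stop("area_min must be < area_max")
  structure(cfg, class = "screening_config")
}

#' Read a screening config from a flat key-value YAML-style file
#'
#' Lines of the form `key: value`; unknown keys are rejected. Missing keys
#' take the [screening_config()] defaults.
#'
#' @param path file path.
#' @export
read_screening_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path, encoding = "UTF-8"),
                value = TRUE, invert = TRUE)
  kv <- strsplit(lines, ":")
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), numeric(1))
  known <- names(formals(screening_config))
  if (any(!keys %in% known)) {
    stop("unknown config key(s): ", paste(setdiff(keys, known), collapse = ", "))
  }
  do.call(screening_config, as.list(stats::setNames(vals, keys)))
}

.verdict <- function(site, criterion, verdict, basis = "computed") {
  stopifnot(verdict %in% VERDICT_LEVELS)
  data.frame(site = site, criterion = criterion, verdict = verdict,
             basis = basis, stringsAsFactors = FALSE)
}

#' Computed criterion verdicts for one site
#'
#' Threshold rules on registry metrics. Missing metrics yield `missing`
#' verdicts, never failures. Geographic isolation fails when the UNEP index
#' is present and below `unep_min` or the SLMP is present and above
#' `slmp_max` (both rules strict, so a site at exactly the cutoff passes);
#' size fails outside `[area_min, area_max]`; topography fails when relief
#' is below `relief_min` (inclusive pass at the threshold).
#'
#' @param site one row of an `island_registry`.
#' @param cfg a [screening_config()].
#' @return one-row verdict data.frame.
#' @name computed_verdicts
#' @export
verdict_geographic_isolation <- function(site, cfg = screening_config()) {
  u <- site$unep_index; s <- site$slmp
  v <- if (is.na(u) && is.na(s)) "missing"
  else if ((!is.na(u) && u < cfg$unep_min) || (!is.na(s) && s > cfg$slmp_max)) "fail"
  else "pass"
  .verdict(site$island, "geographic_isolation", v)
}

#' @rdname computed_verdicts
#' @export
verdict_size <- function(site, cfg = screening_config()) {
  a <- site$area_km2
  v <- if (is.na(a)) "missing"
  else if (a < cfg$area_min || a > cfg$area_max) "fail" else "pass"
  .verdict(site$island, "size", v)
}

#' @rdname computed_verdicts
#' @export
verdict_topography <- function(site, cfg = screening_config()) {
  emax <- site$elevation_max_m
  emin <- if (!is.null(site$elevation_min_m) && !is.na(site$elevation_min_m))
    site$elevation_min_m else 0
  v <- if (is.na(emax)) "missing"
  else if ((emax - emin) < cfg$relief_min) "fail" else "pass"
  .verdict(site$island, "topography", v)
}

#' @rdname computed_verdicts
#' @param richness result of [richness_counts()] for the site, or NULL.
#' @export
verdict_richness <- function(site, richness = NULL, cfg = screening_config()) {
  v <- if (is.null(richness) || richness$n_total == 0) "missing"
  else if (richness$n_total > cfg$richness_max) "fail" else "pass"
  .verdict(site$island, "richness", v)
}

#' @rdname computed_verdicts
#' @export
verdict_target_present <- function(site, richness = NULL) {
  v <- if (is.null(richness) || richness$n_total == 0) "missing"
  else if (richness$target_present) "pass" else "fail"
  .verdict(site$island, "target_present", v)
}

#' Genetic isolation and diversity verdicts
#'
#' Genetic isolation passes when the island-to-nearest-mainland FST meets
#' `fst_isolation_min`. Genetic diversity passes when island nucleotide
#' diversity is significantly lower than the mainland's: rank-sum p below
#' 0.05 and island mean below mainland mean. NULL inputs yield `missing`.
#'
#' @param site one registry row.
#' @param fst_to_mainland numeric FST or NULL.
#' @param pi_comparison result of [rank_sum_compare()] augmented with
#'   `island_mean` and `mainland_mean`, or NULL.
#' @param cfg a [screening_config()].
#' @return two-row verdict data.frame (isolation, diversity).
#' @export
verdict_genetic <- function(site, fst_to_mainland = NULL, pi_comparison = NULL,
                            cfg = screening_config()) {
  iso <- if (is.null(fst_to_mainland) || is.na(fst_to_mainland)) "missing"
  else if (fst_to_mainland >= cfg$fst_isolation_min) "pass" else "fail"
  div <- if (is.null(pi_comparison)) "missing"
  else if (pi_comparison$p_value < 0.05 &&
           pi_comparison$island_mean < pi_comparison$mainland_mean) "pass" else "fail"
  rbind(.verdict(site$island, "genetic_isolation", iso),
        .verdict(site$island, "genetic_diversity", div))
}

#' Computed verdicts for a whole registry
#'
#' Applies every computable threshold rule to each site. Criteria whose
#' inputs are not supplied (species lists, genetics) come back `missing`.
#'
#' @param registry an `island_registry`.
#' @param cfg a [screening_config()].
#' @param species_records optional data.frame from [load_species_records()].
#' @param genetics optional named list per site with elements
#'   `fst_to_mainland` and/or `pi_comparison`.
#' @return verdict data.frame, one row per site x criterion.
#' @export
compute_verdicts <- function(registry, cfg = screening_config(),
                             species_records = NULL, genetics = NULL) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    site <- registry[i, ]
    rich <- if (!is.null(species_records)) richness_counts(species_records, site$island)
    gen <- if (!is.null(genetics)) genetics[[site$island]]
    rbind(verdict_target_present(site, rich),
          verdict_geographic_isolation(site, cfg),
          verdict_genetic(site, gen$fst_to_mainland, gen$pi_comparison, cfg),
          verdict_size(site, cfg),
          verdict_topography(site, cfg),
          verdict_richness(site, rich, cfg))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Load curated verdicts from a wide TSV
#'
#' One row per site, one column per criterion, cells in
#' pass/fail/missing/deferred. The shipped `box2_verdicts.tsv` is the
#' transcription of the published per-site evaluation summary.
#'
#' @param path TSV path.
#' @return long-format verdict data.frame with `basis = "curated"`.
#' @export
load_curated_verdicts <- function(path) {
  wide <- utils::read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  wide$site <- .norm_name(wide$site)
  crits <- setdiff(names(wide), "site")
  out <- do.call(rbind, lapply(crits, function(cc) {
    data.frame(site = wide$site, criterion = cc, verdict = wide[[cc]],
               basis = "curated", stringsAsFactors = FALSE)
  }))
  bad <- !out$verdict %in% VERDICT_LEVELS
  if (any(bad)) stop("invalid verdict value(s): ", paste(unique(out$verdict[bad]), collapse = ", "))
  dup <- duplicated(out[, c("site", "criterion")])
  if (any(dup)) stop("duplicate (site, criterion) verdicts")
  if (any(out$verdict == "deferred" & out$criterion %in% PRIMARY_CRITERIA)) {
    stop("primary criteria may not be deferred")
  }
  out[order(match(out$site, wide$site), match(out$criterion, c(PRIMARY_CRITERIA, SECONDARY_CRITERIA))), ]
}

#' Merge computed and curated verdicts
#'
#' Curated verdicts take precedence when both exist for a (site, criterion)
#' pair; every disagreement on a non-missing computed verdict is reported in
#' the `conflicts` attribute rather than silently resolved (e.g. Bioko's
#' SLMP of 1.148 exceeds the 1.0 cutoff yet its curated geographic-isolation
#' verdict is a pass).
#'
#' @param computed,curated long-format verdict data.frames.
#' @param prefer_curated when FALSE, computed verdicts win instead.
#' @return merged verdicts; disagreements in `attr(, "conflicts")`.
#' @export
merge_verdicts <- function(computed, curated, prefer_curated = TRUE) {
  key <- function(v) paste(v$site, v$criterion, sep = "\r")
  both <- intersect(key(computed), key(curated))
  ci <- match(both, key(computed)); ui <- match(both, key(curated))
  disagree <- computed$verdict[ci] != curated$verdict[ui] &
    computed$verdict[ci] != "missing" & curated$verdict[ui] != "missing"
  conflicts <- data.frame(site = computed$site[ci][disagree],
                          criterion = computed$criterion[ci][disagree],
                          computed = computed$verdict[ci][disagree],
                          curated = curated$verdict[ui][disagree],
                          stringsAsFactors = FALSE)
  loser <- if (prefer_curated) computed else curated
  winner <- if (prefer_curated) curated else computed
  merged <- rbind(winner, loser[!key(loser) %in% key(winner), ])
  rownames(merged) <- NULL
  attr(merged, "conflicts") <- conflicts
  merged
}

#' @rdname merge_verdicts
#' @param verdicts a merged verdict data.frame.
#' @export
verdict_conflicts <- function(verdicts) attr(verdicts, "conflicts")

#' Aggregate per-criterion verdicts into a site status
#'
#' A site is `excluded` when any eliminating primary criterion fails and
#' `candidate` otherwise. Under the default policy, missing data is
#' tolerated (a site is not penalised for unavailable evidence) and the
#' species-richness criterion is advisory: a richness failure alone does
#' not eliminate a site, matching the published decisions in which no site
#' was dropped on richness alone. The `strict` policy demands an explicit
#' pass on all seven primary criteria.
#'
#' @param verdicts long-format verdicts for one site (all seven primary
#'   criteria must be present).
#' @param policy `"default"` or `"strict"`.
#' @param advisory_criteria primary criteria whose failure does not
#'   eliminate under the default policy.
#' @return `"candidate"` or `"excluded"`.
#' @export
aggregate_verdicts <- function(verdicts, policy = c("default", "strict"),
                               advisory_criteria = "richness") {
  policy <- match.arg(policy)
  prim <- verdicts[verdicts$criterion %in% PRIMARY_CRITERIA, ]
  absent <- setdiff(PRIMARY_CRITERIA, prim$criterion)
  if (length(absent)) {
    stop("missing verdict(s) for primary criteria: ", paste(absent, collapse = ", "))
  }
  if (policy == "strict") {
    return(if (all(prim$verdict == "pass")) "candidate" else "excluded")
  }
  eliminating <- setdiff(PRIMARY_CRITERIA, advisory_criteria)
  fails <- prim$verdict == "fail" & prim$criterion %in% eliminating
  if (any(fails)) "excluded" else "candidate"
}

#' Screen all sites and list candidates
#'
#' Runs [aggregate_verdicts()] per site and returns a deterministic,
#' name-sorted status table.
#'
#' @param verdicts long-format verdicts covering all primary criteria for
#'   every site.
#' @inheritParams aggregate_verdicts
#' @return data.frame with `site` and `status`, sorted by site name.
#' @examples
#' v <- load_curated_verdicts(islescreen_example("box2_verdicts.tsv"))
#' s <- screen_sites(v)
#' s$site[s$status == "candidate"]
#' @export
screen_sites <- function(verdicts, policy = "default",
                         advisory_criteria = "richness") {
  sites <- sort(unique(verdicts$site), method = "radix")
  status <- vapply(sites, function(s) {
    aggregate_verdicts(verdicts[verdicts$site == s, ], policy, advisory_criteria)
  }, character(1))
  data.frame(site = sites, status = unname(status), stringsAsFactors = FALSE)
}

#' Render verdicts as a summary matrix
#'
#' One row per site ordered oceanic, then continental, then lacustrine
#' (registry order within type), one column per criterion, with symbols
#' pass = check mark, fail = cross, missing = hyphen, deferred = asterisk.
#' `parse_matrix` is the exact inverse.
#'
#' @param verdicts long-format verdict data.frame.
#' @param registry optional `island_registry` supplying island types for row
#'   ordering; without it, rows are in first-appearance order.
#' @return data.frame of symbols, first column `site`.
#' @export
render_matrix <- function(verdicts, registry = NULL) {
  sites <- unique(verdicts$site)
  if (!is.null(registry)) {
    ord <- order(match(registry$island_type[match(sites, registry$island)],
                       c("oceanic", "continental", "lacustrine")))
    sites <- sites[ord]
  }
  crits <- intersect(c(PRIMARY_CRITERIA, SECONDARY_CRITERIA), unique(verdicts$criterion))
  out <- data.frame(site = sites, stringsAsFactors = FALSE)
  for (cc in crits) {
    v <- verdicts[verdicts$criterion == cc, ]
    out[[cc]] <- VERDICT_SYMBOLS[v$verdict[match(sites, v$site)]]
  }
  out
}

#' @rdname render_matrix
#' @param rendered a data.frame produced by `render_matrix`.
#' @export
parse_matrix <- function(rendered) {
  sym_to_verdict <- stats::setNames(names(VERDICT_SYMBOLS), VERDICT_SYMBOLS)
  crits <- setdiff(names(rendered), "site")
  out <- do.call(rbind, lapply(crits, function(cc) {
    data.frame(site = rendered$site, criterion = cc,
               verdict = unname(sym_to_verdict[rendered[[cc]]]),
               basis = "curated", stringsAsFactors = FALSE)
  }))
  out[order(match(out$site, rendered$site),
            match(out$criterion, c(PRIMARY_CRITERIA, SECONDARY_CRITERIA))), ]
}
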