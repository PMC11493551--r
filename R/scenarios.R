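#' Incursion scenario parameters
#'
#' One incursion configuration: how many founders arrive per introduction
#' event (propagule size, 2-20), across how many events (propagule number,
#' 1-3), where (entry point `site1` or `site2`) and when (1-3 introduction
#' days in simulation days 1-730, the first being the timing of
#' introduction).
#'
#' @param propagule_size founders per introduction event.
#' @param propagule_number number of introduction events (1-3).
#' @param entry_point `"site1"` or `"site2"`.
#' @param intro_days integer days in `[1, 730]`, one per event, ascending.
#' @param propagule_interpretation `"per_event"` (each event introduces
#'   `propagule_size` toads, the default reading) or `"split_total"`
#'   (`propagule_size` toads split as evenly as possible across events).
#' @return a `scenario_params` list.
#' @export
scenario_params <- function(propagule_size, propagule_number = 1L,
                            entry_point = c("site1", "site2"),
                            intro_days,
                            propagule_interpretation = c("per_event", "split_total")) {
  entry_point <- match.arg(entry_point)
  propagule_interpretation <- match.arg(propagule_interpretation)
  if (propagule_size < 1) stop_with("propagule_size must be >= 1")
  propagule_number <- as.integer(propagule_number)
  if (!propagule_number %in% 1:3) stop_with("propagule_number must be 1, 2 or 3")
  intro_days <- as.integer(intro_days)
  if (length(intro_days) != propagule_number)
    stop_with("need %d intro_days, got %d", propagule_number, length(intro_days))
  if (is.unsorted(intro_days) || any(intro_days < 1L) || any(intro_days > 730L))
    stop_with("intro_days must be ascending within [1, 730]")
  structure(list(propagule_size = as.integer(propagule_size),
                 propagule_number = propagule_number,
                 entry_point = entry_point, intro_days = intro_days,
                 propagule_interpretation = propagule_interpretation),
            class = "scenario_params")
}

#' Latin hypercube scenario design
#'
#' Samples `n_combos` scenario parameter combinations over the four
#' design dimensions (propagule size 2-20, propagule number 1-3, entry
#' point, first introduction day 1-730) by Latin hypercube sampling:
#' continuous unit-interval draws with exactly one draw per stratum per
#' dimension, then discretised to the integer levels. Days of second and
#' third events are sampled uniformly after the first. `optimize =
#' "maximin"` draws `n_candidates` candidate hypercubes and keeps the one
#' with the largest minimum pairwise distance.
#'
#' @param n_combos number of parameter combinations (>= 1).
#' @param seed integer seed.
#' @param optimize `"none"` or `"maximin"`.
#' @param n_candidates candidate designs scanned under `"maximin"`.
#' @return a `scenario_design` data frame with columns `combo_id`,
#'   `propagule_size`, `propagule_number`, `entry_point`,
#'   `intro_day_1..3` (`NA` for unused events), carrying the
#'   pre-discretisation draws as attribute `unit_draws`.
#' @export
lhs_design <- function(n_combos, seed, optimize = c("none", "maximin"),
                       n_candidates = 10L) {
  optimize <- match.arg(optimize)
  if (!is.numeric(n_combos) || n_combos < 1) stop_with("n_combos must be >= 1")
  if (missing(seed)) stop_with("lhs_design() requires an explicit seed")
  n <- as.integer(n_combos)
  set.seed(as.integer(seed))
  draw <- function() lhs::randomLHS(n, 4L)
  if (optimize == "maximin" && n > 1) {
    best <- NULL; best_d <- -Inf
    for (i in seq_len(max(2L, as.integer(n_candidates)))) {
      cand <- draw()
      d <- min(stats::dist(cand))
      if (d > best_d) { best <- cand; best_d <- d }
    }
    u <- best
  } else {
    u <- draw()
  }
  ps <- pmin(2L + as.integer(floor(u[, 1] * 19)), 20L)
  pn <- pmin(1L + as.integer(floor(u[, 2] * 3)), 3L)
  se <- ifelse(u[, 3] < 0.5, "site1", "site2")
  d1 <- pmin(1L + as.integer(floor(u[, 4] * 730)), 730L)
  d2 <- rep(NA_integer_, n); d3 <- rep(NA_integer_, n)
  multi <- pn >= 2L
  if (any(multi)) {
    lo <- d1[multi]
    d2[multi] <- lo + as.integer(ceiling(stats::runif(sum(multi)) * pmax(730L - lo, 1L)))
    d2[multi] <- pmin(d2[multi], 730L)
  }
  triple <- pn == 3L
  if (any(triple)) {
    lo <- d1[triple]
    d3[triple] <- lo + as.integer(ceiling(stats::runif(sum(triple)) * pmax(730L - lo, 1L)))
    d3[triple] <- pmin(d3[triple], 730L)
    swap <- !is.na(d2[triple]) & d3[triple] < d2[triple]
    tmp <- d2[triple][swap]
    d2[triple][swap] <- d3[triple][swap]
    d3[triple][swap] <- tmp
  }
  out <- data.frame(combo_id = seq_len(n), propagule_size = ps,
                    propagule_number = pn, entry_point = se,
                    intro_day_1 = d1, intro_day_2 = d2, intro_day_3 = d3,
                    stringsAsFactors = FALSE)
  attr(out, "unit_draws") <- u
  class(out) <- c("scenario_design", "data.frame")
  out
}

#' Enumerate the replicate-level run plan of a design
#'
#' Expands a [lhs_design()] into one row per (combination, replicate) with
#' a derived per-run seed, so a 600-combination design at 30 replicates
#' enumerates 18,000 scenario runs.
#'
#' @param design a `scenario_design`.
#' @param replicates replicates per combination.
#' @param base_seed integer base seed mixed into each run's seed.
#' @return data frame with `combo_id`, `replicate`, `seed` plus the design
#'   columns.
#' @export
enumerate_runs <- function(design, replicates = 30L, base_seed = 1L) {
  stopifnot(nrow(design) >= 1, replicates >= 1)
  idx <- rep(seq_len(nrow(design)), each = replicates)
  out <- design[idx, , drop = FALSE]
  out$replicate <- rep(seq_len(replicates), times = nrow(design))
  out$seed <- mapply(hash_seed, base_seed, out$combo_id, out$replicate)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out[, c("combo_id", "replicate", "seed", "propagule_size", "propagule_number",
          "entry_point", "intro_day_1", "intro_day_2", "intro_day_3")]
}

#' Run one incursion scenario
#'
#' Steps the individual-based simulator daily from the first introduction.
#' Introduction events fire on their scheduled days; cohorts from separate
#' events coexist and interbreed. The run ends `max_years * 365` days
#' after the first introduction, or at extinction (no toads, no clutches,
#' no pending events), whichever comes first. The replicate is scored
#' established when final adult count / total introduced individuals
#' strictly exceeds 1.0.
#'
#' @param params a [scenario_params()].
#' @param land a [landscape()] containing `params$entry_point`, or a named
#'   list of landscapes keyed by entry point.
#' @param rain a `rainfall_series` long enough to cover the run.
#' @param ibm an [ibm_params()] list.
#' @param max_years run length in years from the first introduction.
#' @param seed integer seed for the replicate.
#' @param keep_ledger keep the full daily ledger on the result (memory
#'   heavy for long runs; the ledger is always checked internally when
#'   `check_ledger = TRUE`).
#' @param check_ledger assert the conservation ledger balances every day.
#' @return a `scenario_result` list: `established` (0/1),
#'   `final_adult_count`, `total_introduced`, `extinction_day` (`NA` if
#'   the population persisted), `trajectory` (daily adult counts) and
#'   optionally `ledger`.
#' @export
run_scenario <- function(params, land, rain, ibm = ibm_params(), max_years = 3,
                         seed = 1L, keep_ledger = FALSE, check_ledger = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  if (inherits(land, "toad_landscape")) land <- list(land)
  this_land <- NULL
  for (l in land) if (params$entry_point %in% names(l$entry_points)) this_land <- l
  if (is.null(this_land))
    stop_with("no landscape provides entry point '%s'", params$entry_point)
  entry_cell <- this_land$entry_points[[params$entry_point]]
  set.seed(as.integer(seed))

  sizes <- if (params$propagule_interpretation == "per_event") {
    rep(params$propagule_size, params$propagule_number)
  } else {
    k <- params$propagule_number
    base <- params$propagule_size %/% k
    extra <- params$propagule_size %% k
    pmax(base + (seq_len(k) <= extra), 1L)
  }
  first_day <- params$intro_days[1]
  end_day <- first_day + as.integer(max_years * 365) - 1L
  if (end_day > nrow(rain))
    stop_with("rainfall series too short: need %d days, have %d", end_day, nrow(rain))

  state <- new_sim_state(day = first_day)
  total_introduced <- 0L
  extinction_day <- NA_integer_
  traj <- integer(end_day - first_day + 1L)
  for (day in first_day:end_day) {
    ev <- which(params$intro_days == day)
    for (e in ev) {
      state <- introduce(state, sizes[e], entry_cell, this_land, ibm)
      total_introduced <- total_introduced + sizes[e]
    }
    state <- sim_step(state, this_land, rain, ibm)
    traj[day - first_day + 1L] <- sum(state$toads$stage == 3L)
    empty <- n_toads(state) == 0 && length(state$clutches$n) == 0
    if (empty && !any(params$intro_days > day)) {
      extinction_day <- day
      traj <- traj[seq_len(day - first_day + 1L)]
      break
    }
  }
  if (check_ledger) check_ledger(state$ledger)
  final_adults <- sum(state$toads$stage == 3L)
  structure(list(
    established = as.integer(final_adults / total_introduced > 1.0),
    final_adult_count = final_adults,
    total_introduced = total_introduced,
    extinction_day = extinction_day,
    trajectory = traj,
    ledger = if (keep_ledger) state$ledger else NULL,
    params = params, seed = as.integer(seed)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> PS=%d PN=%d %s day %d: %s (%d adults / %d introduced)%s\n",
              x$params$propagule_size, x$params$propagule_number,
              x$params$entry_point, x$params$intro_days[1],
              if (x$established == 1L) "ESTABLISHED" else "failed",
              x$final_adult_count, x$total_introduced,
              if (!is.na(x$extinction_day)) sprintf(", extinct day %d", x$extinction_day) else ""))
  invisible(x)
}

design_row_params <- function(row, propagule_interpretation = "per_event") {
  days <- c(row$intro_day_1, row$intro_day_2, row$intro_day_3)
  days <- sort(days[!is.na(days)])[seq_len(row$propagule_number)]
  scenario_params(row$propagule_size, row$propagule_number, row$entry_point,
                  days, propagule_interpretation)
}

#' Execute a scenario design with replication
#'
#' Runs every (combination, replicate) pair of [enumerate_runs()] through
#' [run_scenario()] with its derived seed, collecting one outcome row per
#' replicate. A replicate that errors is recorded with `error = 1` and
#' `NA` outcome, never dropped.
#'
#' @param design a [lhs_design()] `scenario_design`.
#' @param landscapes named list of [landscape()]s covering both entry
#'   points (e.g. `list(packed_land, fragmented_land)`).
#' @param rain a `rainfall_series`.
#' @param ibm an [ibm_params()] list.
#' @param replicates replicates per combination (default 30).
#' @param base_seed base seed mixed into per-run seeds.
#' @param max_years run length in years.
#' @param propagule_interpretation see [scenario_params()].
#' @param workers parallel workers via `parallel::mclapply` (default 1).
#' @param progress print a progress line every `progress` runs (0 = quiet).
#' @return an `outcome_table` data frame: `combo_id`, `replicate`, `seed`,
#'   `PS`, `PN`, `SE`, `intro_day`, `established`, `final_adults`,
#'   `total_introduced`, `extinction_day`, `error`.
#' @export
run_batch <- function(design, landscapes, rain, ibm = ibm_params(),
                      replicates = 30L, base_seed = 1L, max_years = 3,
                      propagule_interpretation = "per_event",
                      workers = 1L, progress = 0L) {
  plan <- enumerate_runs(design, replicates, base_seed)
  one <- function(i) {
    row <- plan[i, ]
    res <- tryCatch({
      sp <- design_row_params(row, propagule_interpretation)
      r <- run_scenario(sp, landscapes, rain, ibm, max_years, seed = row$seed)
      c(established = r$established, final_adults = r$final_adult_count,
        total_introduced = r$total_introduced,
        extinction_day = if (is.na(r$extinction_day)) NA_real_ else r$extinction_day,
        error = 0)
    }, error = function(e) {
      c(established = NA_real_, final_adults = NA_real_, total_introduced = NA_real_,
        extinction_day = NA_real_, error = 1)
    })
    if (progress > 0 && i %% progress == 0)
      message(sprintf("run %d/%d", i, nrow(plan)))
    res
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(plan)), one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(plan)), one)
  }
  rm <- do.call(rbind, results)
  out <- data.frame(combo_id = plan$combo_id, replicate = plan$replicate,
                    seed = plan$seed, PS = plan$propagule_size,
                    PN = plan$propagule_number, SE = plan$entry_point,
                    intro_day = plan$intro_day_1,
                    established = rm[, "established"],
                    final_adults = rm[, "final_adults"],
                    total_introduced = rm[, "total_introduced"],
                    extinction_day = rm[, "extinction_day"],
                    error = rm[, "error"], stringsAsFactors = FALSE)
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Coerce a data frame to the modelling outcome table
#'
#' Validates and types the replicate-level table the GLM layer consumes:
#' `PS` integer, `PN` a factor with reference level 1, `SE` a factor with
#' reference level `site1`, `intro_day` in 1-730, `established` binary.
#'
#' @param df data frame with columns `PS`, `PN`, `SE`, `intro_day`,
#'   `established`.
#' @return an `outcome_table` data frame with typed columns.
#' @export
as_outcome_table <- function(df) {
  for (k in c("PS", "PN", "SE", "intro_day", "established"))
    if (!k %in% names(df)) stop_with("outcome table missing column '%s'", k)
  if (anyNA(df[, c("PS", "PN", "SE", "intro_day", "established")]))
    stop_with("outcome table contains missing values")
  if (!all(df$established %in% c(0, 1)))
    stop_with("'established' must be binary 0/1")
  if (any(df$intro_day < 1 | df$intro_day > 730))
    stop_with("'intro_day' must lie in [1, 730]")
  df$PS <- as.integer(df$PS)
  df$PN <- factor(as.integer(as.character(factor(df$PN))), levels = 1:3)
  df$SE <- factor(as.character(df$SE), levels = c("site1", "site2"))
  if (anyNA(df$PN) || anyNA(df$SE))
    stop_with("'PN' must be 1-3 and 'SE' one of site1/site2")
  class(df) <- c("outcome_table", "data.frame")
  df
}

#' Read and write outcome tables
#'
#' Plain CSV with the [run_batch()] column schema (or at minimum the five
#' modelling columns).
#'
#' @param df an outcome table.
#' @param path file path.
#' @return `read_outcomes()` returns an `outcome_table`.
#' @export
write_outcomes <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  as_outcome_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
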