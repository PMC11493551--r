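#' Life-history parameters of the individual-based simulator
#'
#' Returns the default parameter set, optionally overridden by name.
#' Development: eggs hatch into tadpoles after `hatch_days`; each clutch
#' metamorphoses at an age drawn uniformly in
#' `[metamorph_min, metamorph_max]` days; terrestrial toads grow linearly in
#' snout-vent length (SVL) at an individual lognormal rate and change stage
#' at SVL thresholds (metamorph to juvenile at `juvenile_svl_mm`, juvenile
#' to adult at `adult_svl_mm`), calibrated so mean age at adulthood is close
#' to `maturity_mean_days`. Hydric physiology: a fixed fraction of standard
#' body weight is lost per dry day; at 10% loss a toad is dehydrated, at
#' `extreme_dehydration_threshold` extremely dehydrated (it then forgoes
#' everything except rehydrating), and at 40% it desiccates and dies.
#' Mortality: independent per-stage daily probabilities with eggs highest,
#' plus an extra daily removal of eggs sharing a cell with tadpoles
#' (cannibalism and chemical suppression).
#'
#' @param ... named overrides of any default.
#' @return a named list of class `ibm_params`.
#' @export
ibm_params <- function(...) {
  defaults <- list(
    hatch_days = 3L,
    metamorph_min = 34L, metamorph_max = 55L,
    metamorph_svl_mm = 10,
    juvenile_svl_mm = 30,
    adult_svl_mm = 70,
    growth_mm_day = 0.30, growth_cv = 0.20,
    maturity_mean_days = 243,
    fecundity_min = 7675L, fecundity_max = 14288L,
    svl_min_adult = 70, svl_max = 110,
    dehydration_threshold = 0.10,
    extreme_dehydration_threshold = 0.25,
    desiccation_threshold = 0.40,
    daily_water_loss_frac = 0.05,
    inactive_loss_mult = 0.5,
    max_daily_move_m = 1000,
    perception_range_m = 300,
    road_preference_weight = 3,
    mort_egg = 0.20, mort_tadpole = 0.08, mort_metamorph = 0.03,
    mort_juvenile = 0.008, mort_adult = 0.002,
    egg_suppression_frac = 0.5,
    sex_ratio = 0.5,
    intro_svl_mean = 90, intro_svl_sd = 10, intro_svl_range = c(70, 110),
    move_scale_wet_m = 150, move_scale_dry_m = 30,
    heading_sd_wet = 0.6,
    p_active_wet = 0.9, p_active_dry = 0.5,
    n_move_candidates = 4L)
  p <- update_params(defaults, list(...), "ibm")
  for (nm in grep("^(mort_|p_active|sex_ratio)", names(p), value = TRUE))
    assert_prob(p[[nm]], nm)
  if (!(p$dehydration_threshold < p$extreme_dehydration_threshold &&
        p$extreme_dehydration_threshold < p$desiccation_threshold))
    stop_with("hydric thresholds must be ordered dehydration < extreme < desiccation")
  if (p$fecundity_min >= p$fecundity_max)
    stop_with("fecundity_min must be below fecundity_max")
  class(p) <- "ibm_params"
  p
}

#' Hydric state from fractional weight loss
#'
#' Deterministic, monotone classification of water-balance state.
#'
#' @param loss_frac fraction of standard body weight lost to water, in
#'   `[0, 1]` (vectorised).
#' @param params an [ibm_params()] list.
#' @return character vector in `hydrated`, `dehydrated`,
#'   `extremely_dehydrated`, `desiccated`.
#' @export
hydric_state <- function(loss_frac, params = ibm_params()) {
  stopifnot(all(loss_frac >= 0), all(loss_frac <= 1))
  out <- rep("hydrated", length(loss_frac))
  out[loss_frac >= params$dehydration_threshold] <- "dehydrated"
  out[loss_frac >= params$extreme_dehydration_threshold] <- "extremely_dehydrated"
  out[loss_frac >= params$desiccation_threshold] <- "desiccated"
  out
}

LEDGER_COLS <- c("day", "egg", "tadpole", "metamorph", "juvenile", "adult",
                 "introduced", "spawned_eggs", "hatched", "metamorphosed",
                 "matured_juvenile", "matured_adult",
                 "d_egg", "d_tadpole", "d_metamorph", "d_juvenile", "d_adult")

empty_toads <- function() {
  list(id = integer(), sex = integer(), stage = integer(), age = integer(),
       svl = double(), growth = double(), hyd = double(), heading = double(),
       cell = integer(), spawned = logical())
}

empty_clutches <- function() {
  list(cell = integer(), n = integer(), age = integer(), meta_age = integer(),
       stage = integer(), mother = integer())
}

#' Create an empty simulation state
#'
#' @param day first simulation day (1-based; day 1 = 1 January of year 1).
#' @return a `sim_state` object. Toads carry an integer `stage`
#'   (1 metamorph, 2 juvenile, 3 adult) and `sex` (1 male, 2 female);
#'   clutches carry a `stage` (1 egg, 2 tadpole) and a count.
#' @export
new_sim_state <- function(day = 1L) {
  structure(list(
    day = as.integer(day),
    toads = empty_toads(),
    clutches = empty_clutches(),
    next_id = 1L,
    intro_today = 0L,
    ledger = matrix(numeric(0), ncol = length(LEDGER_COLS),
                    dimnames = list(NULL, LEDGER_COLS))),
    class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  st <- tabulate(x$toads$stage, nbins = 3L)
  cl <- c(sum(x$clutches$n[x$clutches$stage == 1L]), sum(x$clutches$n[x$clutches$stage == 2L]))
  cat(sprintf("<sim_state> day %d: %d eggs, %d tadpoles, %d metamorphs, %d juveniles, %d adults\n",
              x$day, cl[1], cl[2], st[1], st[2], st[3]))
  invisible(x)
}

n_toads <- function(state) length(state$toads$id)

# truncated-normal SVL draw via inverse CDF
draw_svl <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

draw_growth <- function(n, params) {
  cv <- params$growth_cv
  if (cv <= 0) return(rep(params$growth_mm_day, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(params$growth_mm_day) - sdlog^2 / 2, sdlog)
}

append_toads <- function(toads, new) {
  for (nm in names(toads)) toads[[nm]] <- c(toads[[nm]], new[[nm]])
  toads
}

subset_toads <- function(toads, keep) {
  for (nm in names(toads)) toads[[nm]] <- toads[[nm]][keep]
  toads
}

#' Introduce founding adults at an entry point
#'
#' Adds `n` adult toads at an entry cell. Sexes are i.i.d. Bernoulli with
#' the configured sex ratio; SVL is drawn from a normal distribution with
#' mean 90 mm truncated to 70-110 mm (the sizes of intercepted stowaway
#' toads); all arrive fully hydrated and unspawned.
#'
#' @param state a [new_sim_state()].
#' @param n number of founders (>= 1).
#' @param entry_cell cell index of the entry point.
#' @param land the [landscape()]; the entry cell must be terrestrial.
#' @param params an [ibm_params()] list.
#' @return the updated `sim_state`.
#' @export
introduce <- function(state, n, entry_cell, land, params = ibm_params()) {
  stopifnot(inherits(state, "sim_state"), n >= 1)
  entry_cell <- as.integer(entry_cell)
  if (land$habitat[entry_cell] == 0L || land$is_water[entry_cell])
    stop_with("entry cell %d is ocean/water; founders must arrive on land", entry_cell)
  n <- as.integer(n)
  ids <- state$next_id + seq_len(n) - 1L
  new <- list(id = ids,
              sex = ifelse(stats::runif(n) < params$sex_ratio, 1L, 2L),
              stage = rep(3L, n),
              age = rep(as.integer(round(params$maturity_mean_days)), n),
              svl = draw_svl(n, params$intro_svl_mean, params$intro_svl_sd,
                             params$intro_svl_range),
              growth = draw_growth(n, params),
              hyd = rep(0, n),
              heading = stats::runif(n, -pi, pi),
              cell = rep(entry_cell, n),
              spawned = rep(FALSE, n))
  state$toads <- append_toads(state$toads, new)
  state$next_id <- state$next_id + n
  state$intro_today <- state$intro_today + n
  state
}

#' Daily behavioural decision
#'
#' Vectorised decision rule. Dehydrated toads prioritise rehydrating
#' regardless of anything else. Otherwise, toads drawn inactive shelter for
#' the day. Active adults breed in the wet season (males repeatedly,
#' females only until they have spawned that season); every other active
#' toad forages.
#'
#' @param stage integer stage (1 metamorph, 2 juvenile, 3 adult).
#' @param sex integer sex (1 male, 2 female).
#' @param has_spawned logical, female has spawned this season.
#' @param hydration_loss fractional body-weight loss.
#' @param season `"wet"` or `"dry"`.
#' @param active logical, the day's activity draw.
#' @param params an [ibm_params()] list.
#' @return character vector in `inactive`, `breeding`, `rehydrating`,
#'   `foraging`.
#' @export
decide_behaviour <- function(stage, sex, has_spawned, hydration_loss, season,
                             active = TRUE, params = ibm_params()) {
  n <- length(stage)
  active <- rep_len(active, n)
  out <- rep("foraging", n)
  can_breed <- stage == 3L & season == "wet" & (sex == 1L | !has_spawned)
  out[can_breed] <- "breeding"
  out[!active] <- "inactive"
  out[hydration_loss >= params$dehydration_threshold] <- "rehydrating"
  out
}

# Draw truncated-exponential step lengths; scale 0 means no movement.
draw_steps <- function(n, scale, max_m, spacing) {
  if (scale <= 0) return(rep(0, n))
  pmin(stats::rexp(n, rate = 1 / scale), max_m - spacing)
}

#' Daily dispersal of terrestrial toads
#'
#' Season-specific displacement: wet-season steps are longer and keep
#' directional persistence; dry-season steps are short with random
#' headings. Rehydrating toads in the dry season head toward their nearest
#' rehydration cell (water margin or human habitation) and never overshoot
#' it; breeding toads head toward the nearest breeding waterbody. Foraging
#' toads pick among candidate destinations with road cells upweighted by
#' `road_preference_weight`. Realised centre-to-centre displacement never
#' exceeds `max_daily_move_m`.
#'
#' @param toads list of parallel vectors with at least `cell`, `heading`,
#'   and `activity` elements (as used inside [sim_step()]).
#' @param land a [landscape()].
#' @param season `"wet"` or `"dry"`.
#' @param rain_today logical, whether it rained today.
#' @param params an [ibm_params()] list.
#' @return list with updated `cell` and `heading` vectors.
#' @export
disperse_toads <- function(toads, land, season, rain_today, params = ibm_params()) {
  n <- length(toads$cell)
  if (n == 0) return(list(cell = toads$cell, heading = toads$heading))
  grid <- land$grid
  activity <- toads$activity
  cache <- ensure_fields(land)
  scale <- if (season == "wet") params$move_scale_wet_m else params$move_scale_dry_m
  cur_xy <- cell_centers(grid, toads$cell)
  new_cell <- toads$cell
  new_head <- toads$heading

  move_mask <- activity != "inactive"
  directed <- activity == "rehydrating" & !(season == "wet" | rain_today)
  directed <- directed | activity == "breeding"
  free <- move_mask & !directed

  place <- function(idx, heading, len) {
    x <- cur_xy[idx, 1] + len * cos(heading)
    y <- cur_xy[idx, 2] + len * sin(heading)
    coords_to_cell(grid, x, y)
  }

  if (any(free)) {
    idx <- which(free)
    K <- params$n_move_candidates
    m <- length(idx)
    if (season == "wet") {
      head_c <- rep(toads$heading[idx], K) + stats::rnorm(m * K, 0, params$heading_sd_wet)
    } else {
      head_c <- stats::runif(m * K, -pi, pi)
    }
    len_c <- draw_steps(m * K, scale, params$max_daily_move_m, grid$spacing_m)
    dest <- place(rep(idx, K), head_c, len_c)
    w <- ifelse(land$is_road[dest], params$road_preference_weight, 1)
    # never step onto water or ocean
    w[land$is_water[dest] | land$habitat[dest] == 0L] <- 0
    wm <- matrix(w, nrow = m)
    dm <- matrix(dest, nrow = m)
    hm <- matrix(head_c, nrow = m)
    tot <- rowSums(wm)
    pick <- rep(1L, m)
    ok <- tot > 0
    if (any(ok)) {
      u <- stats::runif(m) * tot
      cw <- wm
      for (k in 2:K) cw[, k] <- cw[, k] + cw[, k - 1L]
      pick <- max.col(cw >= u, ties.method = "first")
    }
    sel <- cbind(seq_len(m), pick)
    chosen <- dm[sel]
    chosen[!ok] <- toads$cell[idx][!ok]
    new_cell[idx] <- chosen
    new_head[idx] <- hm[sel]
  }

  if (any(directed)) {
    idx <- which(directed)
    rehy <- activity[idx] == "rehydrating"
    fld_r <- cache$rehydration
    fld_b <- cache$breeding
    target <- integer(length(idx))
    target[rehy] <- if (!is.null(fld_r)) fld_r$nearest[toads$cell[idx][rehy]] else 0L
    target[!rehy] <- if (!is.null(fld_b)) fld_b$nearest[toads$cell[idx][!rehy]] else 0L
    has_t <- target > 0L
    if (any(has_t)) {
      ti <- idx[has_t]
      txy <- cell_centers(grid, target[has_t])
      dx <- txy[, 1] - cur_xy[ti, 1]
      dy <- txy[, 2] - cur_xy[ti, 2]
      dist <- sqrt(dx^2 + dy^2)
      heading <- atan2(dy, dx)
      len <- pmin(draw_steps(length(ti), max(scale, params$move_scale_wet_m),
                             params$max_daily_move_m, grid$spacing_m), dist)
      dest <- place(ti, heading, len)
      # breeding toads stop at the margin rather than on open water
      onw <- land$is_water[dest] & activity[ti] == "breeding"
      if (any(onw)) {
        nb <- hex_neighbors(grid, dest[onw])
        land_nb <- apply(nb, 1L, function(r) {
          r <- r[!is.na(r)]
          r <- r[!land$is_water[r] & land$habitat[r] != 0L]
          if (length(r)) r[1] else NA_integer_
        })
        dest[onw] <- ifelse(is.na(land_nb), toads$cell[ti][onw], land_nb)
      }
      bad <- land$is_water[dest] | land$habitat[dest] == 0L
      dest[bad] <- toads$cell[ti][bad]
      new_cell[ti] <- dest
      new_head[ti] <- heading
    }
  }
  list(cell = new_cell, heading = new_head)
}

clutch_size_from_svl <- function(svl, params) {
  s <- pmin(pmax(svl, params$svl_min_adult), params$svl_max)
  frac <- (s - params$svl_min_adult) / (params$svl_max - params$svl_min_adult)
  as.integer(round(params$fecundity_min +
                     frac * (params$fecundity_max - params$fecundity_min)))
}

#' Choose a spawning site and clutch size
#'
#' A breeding female perceives waterbody cells within
#' `perception_range_m` and spawns into the one holding the fewest
#' tadpoles (optimising offspring survival against cannibalism and
#' chemical suppression); ties are broken by proximity, then lowest cell
#' index. Clutch size maps the female's SVL linearly from
#' `[svl_min_adult, svl_max]` onto `[fecundity_min, fecundity_max]`.
#'
#' @param female_svl female snout-vent length (mm).
#' @param female_cell the female's cell index.
#' @param land a [landscape()].
#' @param tadpole_counts named numeric vector of resident tadpole counts
#'   keyed by water-cell index (cells absent count as 0).
#' @param params an [ibm_params()] list.
#' @return `NULL` if no waterbody is perceptible (breeding fails),
#'   otherwise a list with `cell` and `n_eggs`.
#' @export
spawn_clutch <- function(female_svl, female_cell, land, tadpole_counts = numeric(),
                         params = ibm_params()) {
  cache <- ensure_fields(land)
  wc <- cache$water_cells
  if (is.null(wc)) {
    wc <- which(land$is_breeding)
    cache$water_cells <- wc
    cache$water_xy <- cell_centers(land$grid, wc)
  }
  if (length(wc) == 0) return(NULL)
  fxy <- cell_centers(land$grid, female_cell)
  d <- sqrt((cache$water_xy[, 1] - fxy[1])^2 + (cache$water_xy[, 2] - fxy[2])^2)
  inr <- d <= params$perception_range_m
  if (!any(inr)) return(NULL)
  cand <- wc[inr]; cd <- d[inr]
  counts <- rep(0, length(cand))
  if (length(tadpole_counts)) {
    m <- match(as.character(cand), names(tadpole_counts))
    counts[!is.na(m)] <- tadpole_counts[m[!is.na(m)]]
  }
  ord <- order(counts, cd, cand)
  list(cell = cand[ord[1]], n_eggs = clutch_size_from_svl(female_svl, params))
}

#' Apply daily mortality
#'
#' Every egg, tadpole and terrestrial toad survives the day independently
#' with its stage-specific probability. Eggs sharing a cell with tadpoles
#' suffer an additional removal fraction (cannibalism and chemical
#' suppression). Desiccated toads are removed deterministically. Death
#' counts per stage are attached as the `deaths` attribute.
#'
#' @param state a `sim_state`.
#' @param params an [ibm_params()] list.
#' @return the updated `sim_state` with attribute `deaths`, a named vector
#'   of counts for egg/tadpole/metamorph/juvenile/adult.
#' @export
apply_mortality <- function(state, params = ibm_params()) {
  deaths <- c(egg = 0, tadpole = 0, metamorph = 0, juvenile = 0, adult = 0)
  cl <- state$clutches
  if (length(cl$n) > 0) {
    is_egg <- cl$stage == 1L
    p <- ifelse(is_egg, params$mort_egg, params$mort_tadpole)
    surv <- stats::rbinom(length(cl$n), cl$n, 1 - p)
    if (any(is_egg) && any(!is_egg)) {
      tad_cells <- unique(cl$cell[!is_egg & cl$n > 0])
      supp <- is_egg & cl$cell %in% tad_cells
      if (any(supp))
        surv[supp] <- stats::rbinom(sum(supp), surv[supp], 1 - params$egg_suppression_frac)
    }
    deaths["egg"] <- sum(cl$n[is_egg] - surv[is_egg])
    deaths["tadpole"] <- sum(cl$n[!is_egg] - surv[!is_egg])
    cl$n <- as.integer(surv)
    keep <- cl$n > 0L
    for (nm in names(cl)) cl[[nm]] <- cl[[nm]][keep]
    state$clutches <- cl
  }
  td <- state$toads
  if (length(td$id) > 0) {
    p <- c(params$mort_metamorph, params$mort_juvenile, params$mort_adult)[td$stage]
    die <- stats::runif(length(td$id)) < p
    die <- die | td$hyd >= params$desiccation_threshold
    if (any(die)) {
      stg <- td$stage[die]
      deaths["metamorph"] <- deaths["metamorph"] + sum(stg == 1L)
      deaths["juvenile"] <- deaths["juvenile"] + sum(stg == 2L)
      deaths["adult"] <- deaths["adult"] + sum(stg == 3L)
      state$toads <- subset_toads(td, !die)
    }
  }
  attr(state, "deaths") <- deaths
  state
}

#' Advance the simulation one day
#'
#' Executes the fixed daily phase order: environment update (season,
#' wet-season onset resets females' spawned flags), aquatic development
#' (hatching, metamorphosis), behaviour choice, movement, breeding and
#' spawning, hydration update, mortality, then ageing and growth.
#' Reproduction sees post-movement positions; mortality runs after
#' spawning so a same-day spawner can die without losing her clutch. The
#' per-day bookkeeping ledger row is appended before the day counter
#' advances.
#'
#' @param state a `sim_state`.
#' @param land a [landscape()].
#' @param rain a `rainfall_series` covering `state$day`.
#' @param params an [ibm_params()] list.
#' @return the updated `sim_state` with `day` advanced by one.
#' @export
sim_step <- function(state, land, rain, params = ibm_params()) {
  day <- state$day
  if (day > nrow(rain)) stop_with("rainfall series ends before day %d", day)
  season <- rain$season[day]
  rain_today <- rain$rain_mm[day] > 0
  flows <- c(introduced = state$intro_today, spawned_eggs = 0, hatched = 0,
             metamorphosed = 0, matured_juvenile = 0, matured_adult = 0)
  state$intro_today <- 0L

  # 1. environment: wet-season onset resets the females' spawned flags
  if (day_of_year(day) == 305L && length(state$toads$spawned) > 0)
    state$toads$spawned[] <- FALSE

  # 2. aquatic development
  cl <- state$clutches
  if (length(cl$n) > 0) {
    hatch <- cl$stage == 1L & cl$age >= params$hatch_days
    if (any(hatch)) {
      flows["hatched"] <- sum(cl$n[hatch])
      cl$stage[hatch] <- 2L
    }
    emerge <- cl$stage == 2L & cl$age >= cl$meta_age
    if (any(emerge)) {
      counts <- cl$n[emerge]
      total <- sum(counts)
      flows["metamorphosed"] <- total
      if (total > 0) {
        cells <- rep(cl$cell[emerge], counts)
        # metamorphs emerge at the waterbody margin, not on open water
        nb <- hex_neighbors(land$grid, cells)
        land_nb <- nb[, 1L]
        for (k in 1:6) {
          cand <- nb[, k]
          better <- !is.na(cand) & !land$is_water[ifelse(is.na(cand), 1L, cand)] &
            (is.na(land_nb) | land$is_water[ifelse(is.na(land_nb), 1L, land_nb)])
          land_nb[better] <- cand[better]
        }
        land_nb[is.na(land_nb)] <- cells[is.na(land_nb)]
        ids <- state$next_id + seq_len(total) - 1L
        new <- list(id = ids,
                    sex = ifelse(stats::runif(total) < params$sex_ratio, 1L, 2L),
                    stage = rep(1L, total),
                    age = rep(cl$age[emerge], counts),
                    svl = rep(params$metamorph_svl_mm, total),
                    growth = draw_growth(total, params),
                    hyd = rep(0, total),
                    heading = stats::runif(total, -pi, pi),
                    cell = land_nb,
                    spawned = rep(FALSE, total))
        state$toads <- append_toads(state$toads, new)
        state$next_id <- state$next_id + total
      }
      for (nm in names(cl)) cl[[nm]] <- cl[[nm]][!emerge]
    }
    state$clutches <- cl
  }

  td <- state$toads
  nt <- length(td$id)
  if (nt > 0) {
    # 3. behaviour choice
    p_act <- if (season == "wet") params$p_active_wet else params$p_active_dry
    active <- stats::runif(nt) < p_act
    activity <- decide_behaviour(td$stage, td$sex, td$spawned, td$hyd, season,
                                 active, params)
    td$activity <- activity

    # 4. movement
    mv <- disperse_toads(td, land, season, rain_today, params)
    td$cell <- mv$cell
    td$heading <- mv$heading

    # 5. breeding and spawning
    if (season == "wet" && any(activity == "breeding")) {
      fem <- which(activity == "breeding" & td$sex == 2L & !td$spawned)
      mal <- which(activity == "breeding" & td$sex == 1L)
      if (length(fem) > 0 && length(mal) > 0) {
        fxy <- cell_centers(land$grid, td$cell[fem])
        mxy <- cell_centers(land$grid, td$cell[mal])
        tad <- state$clutches$stage == 2L
        tad_counts <- if (any(tad))
          tapply(state$clutches$n[tad], as.character(state$clutches$cell[tad]), sum)
        else numeric()
        for (j in seq_along(fem)) {
          i <- fem[j]
          dm <- sqrt((mxy[, 1] - fxy[j, 1])^2 + (mxy[, 2] - fxy[j, 2])^2)
          near <- which(dm <= params$perception_range_m)
          if (length(near) == 0) next
          mate <- near[sample.int(length(near), 1L)] # stochastic mate selection
          site <- spawn_clutch(td$svl[i], td$cell[i], land, tad_counts, params)
          if (is.null(site)) next
          state$clutches$cell <- c(state$clutches$cell, site$cell)
          state$clutches$n <- c(state$clutches$n, site$n_eggs)
          state$clutches$age <- c(state$clutches$age, 0L)
          state$clutches$meta_age <- c(state$clutches$meta_age,
                                       sample(params$metamorph_min:params$metamorph_max, 1L))
          state$clutches$stage <- c(state$clutches$stage, 1L)
          state$clutches$mother <- c(state$clutches$mother, td$id[i])
          td$spawned[i] <- TRUE
          flows["spawned_eggs"] <- flows["spawned_eggs"] + site$n_eggs
        }
      }
    }

    # 6. hydration update
    if (season == "wet" || rain_today) {
      td$hyd[] <- 0
    } else {
      at_rehy <- land$is_rehydration[td$cell]
      td$hyd[at_rehy] <- 0
      loss <- params$daily_water_loss_frac *
        ifelse(activity == "inactive", params$inactive_loss_mult, 1)
      td$hyd[!at_rehy] <- pmin(td$hyd[!at_rehy] + loss[!at_rehy], 1)
    }
    td$activity <- NULL
    state$toads <- td
  }

  # 7. mortality
  state <- apply_mortality(state, params)
  deaths <- attr(state, "deaths")

  # 8. ageing and growth
  td <- state$toads
  if (length(td$id) > 0) {
    td$age <- td$age + 1L
    td$svl <- pmin(td$svl + td$growth, params$svl_max)
    to_juv <- td$stage == 1L & td$svl >= params$juvenile_svl_mm
    td$stage[to_juv] <- 2L
    to_ad <- td$stage == 2L & td$svl >= params$adult_svl_mm
    td$stage[to_ad] <- 3L
    flows["matured_juvenile"] <- sum(to_juv)
    flows["matured_adult"] <- sum(to_ad)
    state$toads <- td
  }
  if (length(state$clutches$n) > 0)
    state$clutches$age <- state$clutches$age + 1L

  st <- tabulate(state$toads$stage, nbins = 3L)
  is_egg <- state$clutches$stage == 1L
  row <- c(day,
           sum(state$clutches$n[is_egg]), sum(state$clutches$n[!is_egg]),
           st[1], st[2], st[3], flows, deaths)
  state$ledger <- rbind(state$ledger, row)
  state$day <- day + 1L
  attr(state, "deaths") <- NULL
  state
}

#' Check the per-day conservation ledger
#'
#' Verifies the exact bookkeeping identity for every compartment on every
#' recorded day: each stage's standing stock equals the previous stock plus
#' inflows (spawning, hatching, metamorphosis, maturation, introduction)
#' minus outflows (deaths, onward maturation). Transitions and deaths are
#' counted in the order the daily phases execute.
#'
#' @param ledger the `ledger` matrix of a `sim_state` (or a
#'   [run_scenario()] result).
#' @return `TRUE` invisibly if the ledger balances; otherwise an error
#'   naming the first day and compartment that fail.
#' @export
check_ledger <- function(ledger) {
  if (nrow(ledger) == 0) return(invisible(TRUE))
  L <- as.data.frame(ledger)
  prev <- rbind(rep(0, 5), L[-nrow(L), c("egg", "tadpole", "metamorph", "juvenile", "adult")])
  expect <- data.frame(
    egg = prev$egg + L$spawned_eggs - L$hatched - L$d_egg,
    tadpole = prev$tadpole + L$hatched - L$metamorphosed - L$d_tadpole,
    metamorph = prev$metamorph + L$metamorphosed - L$matured_juvenile - L$d_metamorph,
    juvenile = prev$juvenile + L$matured_juvenile - L$matured_adult - L$d_juvenile,
    adult = prev$adult + L$matured_adult + L$introduced - L$d_adult)
  for (nm in names(expect)) {
    bad <- which(L[[nm]] != expect[[nm]])
    if (length(bad))
      stop_with("conservation ledger fails for '%s' on day %d: stock %g, expected %g",
                nm, L$day[bad[1]], L[[nm]][bad[1]], expect[[nm]][bad[1]])
  }
  invisible(TRUE)
}

#' Daily population snapshot
#'
#' @param state a `sim_state`.
#' @return data frame `day,stage,sex,count` for the current population.
#' @export
population_snapshot <- function(state) {
  td <- state$toads
  stages <- c("metamorph", "juvenile", "adult")
  sexes <- c("male", "female")
  if (length(td$id) == 0)
    return(data.frame(day = integer(), stage = character(), sex = character(),
                      count = integer()))
  tab <- table(factor(stages[td$stage], levels = stages),
               factor(sexes[td$sex], levels = sexes))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("stage", "sex", "count")
  cbind(day = state$day, df)
}
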