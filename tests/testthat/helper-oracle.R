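# Independent straight-line reference implementation of the whole
# accounting: hand-coded interpolation, explicit loops over every
# (cohort, year) pair, and a literal transcription of the yearly
# maintain/increase steps. Deliberately unvectorised and shares no code
# with the package functions it checks.

oracle_interp_5px <- function(life_table, e0, age) {
  lv <- life_table$levels
  starts <- sort(unique(lv$age_group_start))
  grp <- NA_real_
  for (s in starts) if (age >= s && age < s + 5) grp <- s
  if (is.na(grp)) stop("oracle: age out of range")
  sub <- lv[lv$age_group_start == grp, , drop = FALSE]
  sub <- sub[order(sub$e0_level), , drop = FALSE]
  n <- nrow(sub)
  if (e0 <= sub$e0_level[1]) return(sub$p5x[1])
  if (e0 >= sub$e0_level[n]) return(sub$p5x[n])
  for (i in seq_len(n - 1)) {
    if (e0 >= sub$e0_level[i] && e0 <= sub$e0_level[i + 1]) {
      w <- (e0 - sub$e0_level[i]) / (sub$e0_level[i + 1] - sub$e0_level[i])
      return(sub$p5x[i] * (1 - w) + sub$p5x[i + 1] * w)
    }
  }
}

oracle_e0 <- function(assumptions, year) {
  d <- assumptions$demography
  if (year %in% d$year) return(d$e0[d$year == year])
  below <- max(d$year[d$year < year]); above <- min(d$year[d$year > year])
  w <- (year - below) / (above - below)
  d$e0[d$year == below] * (1 - w) + d$e0[d$year == above] * w
}

oracle_denominator <- function(assumptions, year) {
  d <- assumptions$demography
  i <- which(d$year == year)
  if (assumptions$cpr_basis == "in-union") d$wra[i] * d$prop_in_union[i]
  else d$wra[i]
}

# Trajectory of one LAPM cohort as a named (by offset) vector, truncated
# at calendar year `horizon`.
oracle_trajectory <- function(units, method, provision_year, assumptions,
                              horizon) {
  traj <- c()
  if (method$category == "long-acting") {
    for (n in 0:(method$max_duration - 1)) {
      if (provision_year + n > horizon) break
      traj[as.character(n)] <- units * (method$ccr[n + 1] + method$ccr[n + 2]) / 2
    }
  } else {
    age0 <- assumptions$median_age_sterilisation
    u <- units
    n <- 0
    while (age0 + n <= 49 && provision_year + n <= horizon) {
      e0 <- oracle_e0(assumptions, provision_year + n)
      p <- oracle_interp_5px(assumptions$life_table, e0, age0 + n)
      u <- u * p^(1 / 5)
      traj[as.character(n)] <- u
      n <- n + 1
    }
  }
  traj
}

# Modelled users in `year`: double loop over all cohorts plus the year's
# short-term division. `max_provision_year` restricts to old cohorts
# (pre-existing view).
oracle_users_in_year <- function(history, assumptions, year,
                                 exclude = "condom",
                                 max_provision_year = Inf) {
  lapm <- 0
  st <- 0
  for (i in seq_len(nrow(history))) {
    mn <- history$method[i]
    if (mn %in% exclude) next
    m <- assumptions$methods[[mn]]
    if (m$category == "short-term") {
      if (history$year[i] == year) st <- st + history$units[i] / m$units_per_year
      next
    }
    if (history$year[i] > max_provision_year || history$year[i] > year) next
    traj <- oracle_trajectory(history$units[i], m, history$year[i],
                              assumptions, year)
    off <- as.character(year - history$year[i])
    if (off %in% names(traj)) lapm <- lapm + traj[[off]]
  }
  list(lapm = lapm, short_term = st, total = lapm + st)
}

oracle_new_users <- function(history, assumptions, year, exclude) {
  by_m <- c()
  for (i in seq_len(nrow(history))) {
    if (history$year[i] != year) next
    mn <- history$method[i]
    if (mn %in% exclude || history$units[i] <= 0) next
    m <- assumptions$methods[[mn]]
    nu <- if (m$category == "long-acting")
      history$units[i] * (m$ccr[1] + m$ccr[2]) / 2
    else if (m$category == "permanent") {
      e0 <- oracle_e0(assumptions, year)
      p <- oracle_interp_5px(assumptions$life_table, e0,
                             assumptions$median_age_sterilisation)
      history$units[i] * p^(1 / 5)
    } else history$units[i] / m$units_per_year
    by_m[mn] <- nu
  }
  by_m
}

# Straight-line steps 1-8.
oracle_trend <- function(history, assumptions, profile_df, y_start, y_end,
                         exclude = "condom") {
  y0 <- y_start - 1
  years <- y_start:y_end
  baseline_users <- oracle_users_in_year(history, assumptions, y0, exclude)$total
  baseline_contrib <- baseline_users / oracle_denominator(assumptions, y0)
  existing <- setNames(numeric(length(years)), years)
  prev_total <- baseline_users
  out <- NULL
  for (y in years) {
    yc <- as.character(y)
    pre <- oracle_users_in_year(history, assumptions, y, exclude,
                                max_provision_year = y0)$lapm
    new_by_m <- oracle_new_users(history, assumptions, y, exclude)
    new_total <- if (length(new_by_m)) sum(new_by_m) else 0
    needed <- prev_total - pre - existing[[yc]]
    if (needed < 0) needed <- 0
    prow <- profile_df[profile_df$year == y, ]
    if (nrow(prow) == 0) prow <- profile_df[1, ]
    C <- new_total * prow$continuers
    A <- new_total * prow$adopters
    if (C >= needed) { maintain <- needed; increase <- A; situation <- 1 }
    else if (C + A <= needed) { maintain <- C + A; increase <- 0; situation <- 2 }
    else { maintain <- needed; increase <- A - (needed - C); situation <- 3 }
    f <- if (new_total == 0) 0 else (maintain + increase) / new_total
    for (mn in names(new_by_m)) {
      m <- assumptions$methods[[mn]]
      if (m$category == "short-term") next
      units <- sum(history$units[history$year == y & history$method == mn])
      traj <- oracle_trajectory(units, m, y, assumptions, y_end)
      for (off in names(traj)) {
        n <- as.integer(off)
        if (n < 1) next
        yy <- as.character(y + n)
        if (yy %in% names(existing))
          existing[[yy]] <- existing[[yy]] + f * traj[[off]]
      }
    }
    total <- pre + existing[[yc]] + maintain + increase
    pct <- 100 * total / oracle_denominator(assumptions, y)
    out <- rbind(out, data.frame(
      year = y, pre_existing = pre, existing = existing[[yc]],
      new_users = new_total, situation = situation, maintain = maintain,
      increase = increase, counting_fraction = f,
      total_users_in_cpr = total, total_pct_contribution = pct,
      pct_point_increase = pct - 100 * baseline_contrib))
    prev_total <- total
  }
  list(baseline_users = baseline_users, baseline_contrib = baseline_contrib,
       years = out)
}
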