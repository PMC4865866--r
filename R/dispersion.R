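# Assembly of per-Q fits into dispersion branches and the derived physical
# quantities: sound speeds, zone-boundary Q_min, area per lipid, damping
# ratios, and the transverse phononic band gap / cluster size.

#' Assemble longitudinal and transverse dispersion branches
#'
#' Turns a per-Q fit table (from [fit_dataset()]) into a tidy branch table.
#' The longitudinal branch is populated at every successfully fitted Q; the
#' transverse branch only where the two-mode model was selected, with
#' `present = FALSE` rows encoding the gap elsewhere.
#'
#' @param fits A tibble from [fit_dataset()] (needs columns `q`, `ok`,
#'   `chosen_n_modes`, `fit`).
#' @return A tibble of class `ixs_branches`: `q`, `branch`, `present`,
#'   `omega`, `omega_err`, `gamma`, `gamma_err`, `intensity` (meV /
#'   counts meV; `NA` where the mode is absent).
#' @export
assemble_branches <- function(fits) {
  stopifnot(is.data.frame(fits), nrow(fits) > 0L,
            all(c("q", "ok", "fit") %in% names(fits)))
  fits <- fits[fits$ok, , drop = FALSE]
  if (nrow(fits) == 0L) stop("no successful fits to assemble.", call. = FALSE)
  if (anyDuplicated(fits$q)) stop("duplicate Q values in fit table.", call. = FALSE)
  fits <- fits[order(fits$q), , drop = FALSE]

  rows <- purrr::map2(fits$fit, fits$q, function(fit, q) {
    tt <- tidy(fit)
    one_branch <- function(br) {
      idx <- which(!is.na(tt$branch) & tt$branch == br)
      if (length(idx) == 0L) {
        return(tibble::tibble(q = q, branch = br, present = FALSE,
                              omega = NA_real_, omega_err = NA_real_,
                              gamma = NA_real_, gamma_err = NA_real_,
                              intensity = NA_real_))
      }
      est <- stats::setNames(tt$estimate[idx], sub("[0-9]+$", "", tt$term[idx]))
      err <- stats::setNames(tt$std.error[idx], sub("[0-9]+$", "", tt$term[idx]))
      tibble::tibble(q = q, branch = br, present = TRUE,
                     omega = est[["omega"]], omega_err = err[["omega"]],
                     gamma = est[["gamma"]], gamma_err = err[["gamma"]],
                     intensity = est[["intensity"]])
    }
    dplyr::bind_rows(one_branch("longitudinal"), one_branch("transverse"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ixs_branches", class(out))
  out
}

branch_subset <- function(branches, branch) {
  stopifnot(is.data.frame(branches),
            all(c("q", "branch", "present", "omega") %in% names(branches)))
  out <- branches[branches$branch == branch, , drop = FALSE]
  out[order(out$q), , drop = FALSE]
}

#' High-frequency sound speed from the low-Q dispersion slope
#'
#' Weighted least-squares line through the origin, `omega = s * Q`, over the
#' present points with `Q <= q_linear_max` (an acoustic branch has
#' `omega(0) = 0`). The slope in meV nm is converted with
#' 1519.2674 m/s per meV nm (from hbar and the unit definitions).
#'
#' @param branches An [assemble_branches()] table (or any tibble with
#'   `q`, `branch`, `present`, `omega`, `omega_err`).
#' @param branch `"longitudinal"` (default) or `"transverse"`.
#' @param q_linear_max Upper end of the linear window in nm^-1 (defaults:
#'   8 longitudinal, 10 transverse).
#' @return A one-row tibble: `branch`, `slope_mev_nm`, `slope_err`,
#'   `speed_m_s`, `speed_err_m_s`, `n_points`.
#' @export
sound_speed <- function(branches, branch = "longitudinal",
                        q_linear_max = if (branch == "longitudinal") 8 else 10) {
  b <- branch_subset(branches, branch)
  b <- b[b$present & b$q <= q_linear_max & !is.na(b$omega), , drop = FALSE]
  if (nrow(b) < 2L) {
    stop("need at least 2 present points with Q <= q_linear_max.", call. = FALSE)
  }
  w <- if (all(is.finite(b$omega_err)) && all(b$omega_err > 0)) {
    1 / b$omega_err^2
  } else {
    rep(1, nrow(b))
  }
  slope <- sum(w * b$q * b$omega) / sum(w * b$q^2)
  slope_var <- if (all(is.finite(b$omega_err)) && all(b$omega_err > 0)) {
    1 / sum(w * b$q^2)
  } else {
    # unweighted: residual-based variance estimate
    res <- b$omega - slope * b$q
    sum(res^2) / max(nrow(b) - 1L, 1L) / sum(b$q^2)
  }
  tibble::tibble(branch = branch, slope_mev_nm = slope,
                 slope_err = sqrt(slope_var),
                 speed_m_s = slope * SLOPE_TO_SPEED,
                 speed_err_m_s = sqrt(slope_var) * SLOPE_TO_SPEED,
                 n_points = nrow(b))
}

#' Locate the dispersion minimum Q_min (quasi-Brillouin-zone boundary)
#'
#' Fits a local parabola around the lowest-omega present point inside the
#' search window (the point and up to two neighbours on each side, at least
#' three points, weighted by the omega errors) and returns the vertex
#' abscissa. The Q resolution of the experiment (~1.5 nm^-1) makes direct
#' minimum picking too coarse, hence the parabolic interpolation; using up
#' to five local points rather than the minimal three keeps the vertex
#' stable against single-point noise while remaining local to the valley.
#' A minimum sitting at the window edge, or a vertex escaping the window,
#' is flagged rather than silently returned.
#'
#' @param branches An [assemble_branches()] table.
#' @param branch Branch to search (default longitudinal).
#' @param window Numeric `c(lo, hi)` in nm^-1 (default `c(10, 20)`).
#' @return A one-row tibble: `branch`, `q_min`, `q_min_err` (delta-method
#'   propagation of the omega errors through the vertex), `omega_min`,
#'   `at_edge`.
#' @export
find_q_min <- function(branches, branch = "longitudinal", window = c(10, 20)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  b <- branch_subset(branches, branch)
  b <- b[b$present & !is.na(b$omega), , drop = FALSE]
  inside <- which(b$q >= window[1] & b$q <= window[2])
  if (length(inside) < 3L) {
    stop("need at least 3 present points inside the search window.",
         call. = FALSE)
  }
  i_min <- inside[which.min(b$omega[inside])]
  at_edge <- i_min == inside[1L] || i_min == inside[length(inside)]
  if (at_edge) {
    return(tibble::tibble(branch = branch, q_min = b$q[i_min],
                          q_min_err = NA_real_, omega_min = b$omega[i_min],
                          at_edge = TRUE))
  }
  idx <- intersect((i_min - 2L):(i_min + 2L), inside)
  qx <- b$q[idx]
  sig <- b$omega_err[idx]
  w <- if (all(is.finite(sig)) && all(sig > 0)) 1 / sig^2 else rep(1, length(idx))
  vertex <- function(om) {
    X <- cbind(1, qx, qx^2)
    co <- solve(crossprod(X * sqrt(w)), crossprod(X * w, om))
    if (co[3] <= 0) return(NA_real_)
    -co[2] / (2 * co[3])
  }
  qv <- vertex(b$omega[idx])
  if (is.na(qv)) {
    return(tibble::tibble(branch = branch, q_min = b$q[i_min],
                          q_min_err = NA_real_, omega_min = b$omega[i_min],
                          at_edge = TRUE))
  }
  # delta method through the omega values
  grad <- vapply(seq_along(idx), function(k) {
    h <- max(abs(b$omega[idx[k]]) * 1e-6, 1e-8)
    om <- b$omega[idx]; om[k] <- om[k] + h
    (vertex(om) - qv) / h
  }, numeric(1))
  q_err <- if (all(is.finite(sig))) sqrt(sum((grad * sig)^2)) else NA_real_
  out_of_window <- qv < window[1] || qv > window[2]
  tibble::tibble(branch = branch, q_min = qv, q_min_err = q_err,
                 omega_min = min(b$omega[idx]),
                 at_edge = out_of_window)
}

#' Area per lipid from the zone-boundary Q_min
#'
#' The mean inter-chain spacing is `d = 2*pi/Q_min`; the in-plane area per
#' lipid molecule follows the simplified relation
#' `A_L = 2.64 * (9*d/8)^2` with `d` in Angstrom.
#'
#' @param q_min Zone-boundary position(s) in nm^-1 (> 0). Vectorized.
#' @param q_min_err Optional 1-sigma error(s) on `q_min`, propagated.
#' @return A tibble: `q_min`, `d_A` (chain spacing, Angstrom), `area_A2`,
#'   and `area_err_A2` when `q_min_err` is given.
#' @export
#' @examples
#' area_per_lipid(c(15.4, 14.2))
area_per_lipid <- function(q_min, q_min_err = NULL) {
  if (!is.numeric(q_min) || any(is.na(q_min)) || any(q_min <= 0)) {
    stop("`q_min` must be positive (nm^-1).", call. = FALSE)
  }
  d_A <- 2 * pi / q_min * 10  # nm -> Angstrom
  area <- 2.64 * (9 * d_A / 8)^2
  out <- tibble::tibble(q_min = q_min, d_A = d_A, area_A2 = area)
  if (!is.null(q_min_err)) {
    # |dA/dq| = 2 * A / q
    out$area_err_A2 <- 2 * area / q_min * q_min_err
  }
  out
}

#' Damping ratio R = omega/Gamma along a branch
#'
#' `R > 1` marks underdamped (propagating) modes, `R < 1` overdamped
#' (diffusive) ones that decay within a single oscillation; `R = 1` is the
#' crossover. A point is classified critically damped when `|R - 1|` is
#' within its propagated 1-sigma error.
#'
#' @param branches An [assemble_branches()] table.
#' @return The input with columns `R`, `R_err` and `regime`
#'   (`"overdamped"`, `"critical"`, `"underdamped"`) added; absent points
#'   get `NA`.
#' @export
damping_ratio <- function(branches) {
  stopifnot(is.data.frame(branches),
            all(c("omega", "gamma", "present") %in% names(branches)))
  if (any(branches$present & (is.na(branches$gamma) | branches$gamma <= 0))) {
    stop("`gamma` must be positive at present points.", call. = FALSE)
  }
  R <- ifelse(branches$present, branches$omega / branches$gamma, NA_real_)
  R_err <- ifelse(
    branches$present &
      is.finite(branches$omega_err) & is.finite(branches$gamma_err),
    sqrt((branches$omega_err / branches$gamma)^2 +
           (branches$omega * branches$gamma_err / branches$gamma^2)^2),
    NA_real_)
  regime <- rep(NA_character_, nrow(branches))
  ok <- branches$present & !is.na(R)
  tol <- ifelse(is.na(R_err), 0, R_err)
  regime[ok] <- dplyr::case_when(
    abs(R[ok] - 1) <= tol[ok] ~ "critical",
    R[ok] < 1 ~ "overdamped",
    TRUE ~ "underdamped")
  branches$R <- R
  branches$R_err <- R_err
  branches$regime <- regime
  branches
}

#' Detect the low-Q transverse phononic band gap
#'
#' The gap is identified as a contiguous run of absent transverse points at
#' the low-Q end of the measured range. Its edge is reported as the midpoint
#' between the largest absent Q of that run and the smallest present Q above
#' it, together with the bracketing interval (the Q resolution of the scan
#' limits anything sharper). No gap is reported when the branch is present
#' at its lowest measured Q.
#'
#' @param branches An [assemble_branches()] table.
#' @param branch Branch to inspect (default `"transverse"`).
#' @return A one-row tibble: `gap_found`, `q_gap` (midpoint, nm^-1),
#'   `q_lo`, `q_hi` (bracketing interval), `note`.
#' @export
detect_phonon_gap <- function(branches, branch = "transverse") {
  b <- branch_subset(branches, branch)
  if (nrow(b) == 0L) stop("branch not found in table.", call. = FALSE)
  no_gap <- tibble::tibble(gap_found = FALSE, q_gap = NA_real_,
                           q_lo = NA_real_, q_hi = NA_real_,
                           note = NA_character_)
  if (b$present[1L]) {
    no_gap$note <- "branch present at lowest measured Q; no gap"
    return(no_gap)
  }
  if (!any(b$present)) {
    warning("no transverse branch detected at any Q.", call. = FALSE)
    no_gap$note <- "no transverse branch detected at any Q"
    return(no_gap)
  }
  first_present <- which(b$present)[1L]
  tibble::tibble(gap_found = TRUE,
                 q_gap = (b$q[first_present - 1L] + b$q[first_present]) / 2,
                 q_lo = b$q[first_present - 1L],
                 q_hi = b$q[first_present],
                 note = NA_character_)
}

#' Dynamic cluster size from the gap edge
#'
#' `d_gap = 2*pi/Q_gap`, the characteristic size of the short-lived local
#' lipid ordering below which transverse sound still propagates.
#'
#' @param q_gap Gap-edge position(s) in nm^-1 (> 0). Vectorized.
#' @return A tibble: `q_gap`, `d_gap_nm`.
#' @export
#' @examples
#' cluster_size(5)
cluster_size <- function(q_gap) {
  if (!is.numeric(q_gap) || any(is.na(q_gap)) || any(q_gap <= 0)) {
    stop("`q_gap` must be positive (nm^-1).", call. = FALSE)
  }
  tibble::tibble(q_gap = q_gap, d_gap_nm = 2 * pi / q_gap)
}

#' All derived quantities of an assembled dispersion
#'
#' Convenience wrapper computing sound speeds, `Q_min`, the chain spacing
#' and area per lipid, the transverse band gap and cluster size from a
#' branch table.
#'
#' @param branches An [assemble_branches()] table.
#' @param q_linear_max_long,q_linear_max_trans Linear-window upper ends for
#'   the two branches (nm^-1).
#' @param q_min_window Search window for the longitudinal dispersion
#'   minimum (nm^-1).
#' @return A one-row tibble with `v_long`, `v_long_err`, `v_trans`,
#'   `v_trans_err` (m/s), `q_min`, `q_min_err`, `q_min_at_edge`, `d_A`,
#'   `area_A2`, `area_err_A2`, `gap_found`, `q_gap`, `q_gap_lo`, `q_gap_hi`,
#'   `d_gap_nm`, `d_gap_lo_nm`, `d_gap_hi_nm`. Quantities that cannot be
#'   computed (for example the transverse speed when the branch is sparse)
#'   are `NA`.
#' @export
derived_quantities <- function(branches, q_linear_max_long = 8,
                               q_linear_max_trans = 10,
                               q_min_window = c(10, 20)) {
  vl <- tryCatch(sound_speed(branches, "longitudinal", q_linear_max_long),
                 error = function(e) NULL)
  vt <- tryCatch(sound_speed(branches, "transverse", q_linear_max_trans),
                 error = function(e) NULL)
  qm <- tryCatch(find_q_min(branches, "longitudinal", q_min_window),
                 error = function(e) NULL)
  gap <- withCallingHandlers(
    detect_phonon_gap(branches, "transverse"),
    warning = function(w) invokeRestart("muffleWarning"))
  ar <- if (!is.null(qm) && !qm$at_edge) {
    area_per_lipid(qm$q_min, qm$q_min_err)
  } else NULL
  tibble::tibble(
    v_long = if (is.null(vl)) NA_real_ else vl$speed_m_s,
    v_long_err = if (is.null(vl)) NA_real_ else vl$speed_err_m_s,
    v_trans = if (is.null(vt)) NA_real_ else vt$speed_m_s,
    v_trans_err = if (is.null(vt)) NA_real_ else vt$speed_err_m_s,
    q_min = if (is.null(qm)) NA_real_ else qm$q_min,
    q_min_err = if (is.null(qm)) NA_real_ else qm$q_min_err,
    q_min_at_edge = if (is.null(qm)) NA else qm$at_edge,
    d_A = if (is.null(ar)) NA_real_ else ar$d_A,
    area_A2 = if (is.null(ar)) NA_real_ else ar$area_A2,
    area_err_A2 = if (is.null(ar) || is.null(ar$area_err_A2)) NA_real_ else ar$area_err_A2,
    gap_found = gap$gap_found,
    q_gap = gap$q_gap,
    q_gap_lo = gap$q_lo,
    q_gap_hi = gap$q_hi,
    d_gap_nm = if (gap$gap_found) 2 * pi / gap$q_gap else NA_real_,
    d_gap_lo_nm = if (gap$gap_found) 2 * pi / gap$q_hi else NA_real_,
    d_gap_hi_nm = if (gap$gap_found) 2 * pi / gap$q_lo else NA_real_)
}
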