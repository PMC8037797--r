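#' Two-channel nucleus specification
#'
#' Describes a synthetic two-colour nucleus: channel B carries the
#' chromatin context (heterochromatin domains labelled, e.g., by H3K9me3,
#' as dense circular domains over a homogeneous background) and channel A
#' carries DNA-damage focus clusters (e.g. \eqn{\gamma}H2AX), each flagged as
#' heterochromatin-associated (HC, centre inside a domain) or not (nHC).
#' The flags are validated against the geometry so the ground truth is
#' always consistent.
#'
#' @param field a [field_spec()].
#' @param hc_domains data.frame with columns `x_nm`, `y_nm`, `radius_nm`,
#'   `n_points`: circular heterochromatin domains in channel B.
#' @param foci data.frame with columns `x_nm`, `y_nm`, `radius_nm`,
#'   `n_points`, `hc_associated` (logical): damage focus clusters in
#'   channel A.
#' @param background_a,background_b homogeneous background event counts in
#'   channels A and B.
#' @param seed integer seed used by [simulate_two_channel()].
#' @return An object of class `two_channel_spec`.
#' @export
two_channel_spec <- function(field, hc_domains, foci, background_a = 0,
                             background_b = 0, seed = 1) {
  hc_domains <- as.data.frame(hc_domains)
  foci <- as.data.frame(foci)
  need_d <- c("x_nm", "y_nm", "radius_nm", "n_points")
  if (nrow(hc_domains) && !all(need_d %in% names(hc_domains)))
    stop("`hc_domains` needs columns ", paste(need_d, collapse = ", "),
         call. = FALSE)
  if (nrow(foci) && !all(c(need_d, "hc_associated") %in% names(foci)))
    stop("`foci` needs columns ", paste(c(need_d, "hc_associated"),
                                        collapse = ", "), call. = FALSE)
  # geometric consistency of the HC flags
  if (nrow(foci)) {
    inside <- vapply(seq_len(nrow(foci)), function(i) {
      if (!nrow(hc_domains)) return(FALSE)
      d <- sqrt((hc_domains$x_nm - foci$x_nm[i])^2 +
                  (hc_domains$y_nm - foci$y_nm[i])^2)
      any(d <= hc_domains$radius_nm)
    }, logical(1))
    if (!identical(inside, as.logical(foci$hc_associated)))
      stop("`hc_associated` flags inconsistent with focus placement",
           call. = FALSE)
  }
  structure(list(field = field, hc_domains = hc_domains, foci = foci,
                 background_a = as.integer(background_a),
                 background_b = as.integer(background_b),
                 seed = as.integer(seed)),
            class = "two_channel_spec")
}

#' Randomly drawn two-channel nucleus specification
#'
#' Convenience generator for [two_channel_spec()] fixtures with a known
#' heterochromatin-association fraction. Domain centres are placed with a
#' mutual separation of two domain radii; HC foci are placed so the whole
#' focus disc lies inside a domain; nHC foci are kept at least
#' `clearance_nm` outside every domain boundary. The number of points per
#' domain is derived from `density_contrast`, the ratio of the added
#' within-domain point density to the channel-B background density.
#'
#' Defaults emulate a HeLa nucleus 2D projection: a 10 x 10 um field,
#' 500-nm heterochromatin domains at 5x background density, and 200-nm
#' damage foci of 60 events each.
#'
#' @param n_domains,domain_radius_nm heterochromatin domain count/radius.
#' @param n_foci,focus_radius_nm,focus_points damage focus count, radius
#'   and events per focus.
#' @param hc_fraction fraction of foci placed inside heterochromatin
#'   domains (rounded to a whole focus count).
#' @param background_a,background_b homogeneous background counts.
#' @param density_contrast within-domain over background density ratio in
#'   channel B.
#' @param clearance_nm extra distance between nHC focus centres and domain
#'   boundaries.
#' @param field a [field_spec()].
#' @param seed integer seed.
#' @return A `two_channel_spec`.
#' @export
random_two_channel_spec <- function(n_domains = 12, domain_radius_nm = 500,
                                    n_foci = 20, focus_radius_nm = 200,
                                    focus_points = 60, hc_fraction = 0.5,
                                    background_a = 1000,
                                    background_b = 20000,
                                    density_contrast = 5,
                                    clearance_nm = 500,
                                    field = field_spec(10000, 10000),
                                    seed = 1) {
  if (focus_radius_nm >= domain_radius_nm && hc_fraction > 0 && n_foci > 0)
    stop("focus radius must be smaller than the domain radius", call. = FALSE)
  bg_density <- background_b / field_area(field)
  pts_per_domain <- max(1L, as.integer(round(
    density_contrast * bg_density * pi * domain_radius_nm^2)))
  n_hc <- as.integer(round(hc_fraction * n_foci))

  withr::with_seed(seed, {
    dspec <- cluster_pattern_spec(
      n_domains, 1, domain_radius_nm,
      min_separation_nm = 2 * domain_radius_nm + clearance_nm)
    centers <- draw_centers(dspec, field)
    hc_domains <- data.frame(x_nm = centers[, 1], y_nm = centers[, 2],
                             radius_nm = domain_radius_nm,
                             n_points = pts_per_domain)
    foci <- NULL
    if (n_foci > 0) {
      fx <- fy <- numeric(n_foci)
      assoc <- c(rep(TRUE, n_hc), rep(FALSE, n_foci - n_hc))
      for (i in seq_len(n_foci)) {
        if (assoc[i]) {
          dom <- ((i - 1L) %% n_domains) + 1L
          off <- rdisc(1, domain_radius_nm - focus_radius_nm)
          fx[i] <- centers[dom, 1] + off[1]
          fy[i] <- centers[dom, 2] + off[2]
        } else {
          ok <- FALSE
          for (try in seq_len(10000L)) {
            cand <- runif_field(1, field)
            d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
            placed <- seq_len(i - 1L)
            d_foci <- if (length(placed))
              sqrt((fx[placed] - cand[1])^2 + (fy[placed] - cand[2])^2)
            else Inf
            margin <- field$origin + focus_radius_nm
            if (all(d > domain_radius_nm + clearance_nm) &&
                all(d_foci > 2 * focus_radius_nm + 100) &&
                cand[1] >= margin[1] && cand[2] >= margin[2] &&
                cand[1] <= field$origin[1] + field$width_nm - focus_radius_nm &&
                cand[2] <= field$origin[2] + field$height_nm - focus_radius_nm) {
              fx[i] <- cand[1]; fy[i] <- cand[2]; ok <- TRUE; break
            }
          }
          if (!ok) stop("could not place a non-HC focus; ",
                        "field too crowded", call. = FALSE)
        }
      }
      foci <- data.frame(x_nm = fx, y_nm = fy, radius_nm = focus_radius_nm,
                         n_points = focus_points, hc_associated = assoc)
    } else {
      foci <- data.frame(x_nm = numeric(), y_nm = numeric(),
                         radius_nm = numeric(), n_points = integer(),
                         hc_associated = logical())
    }
    two_channel_spec(field, hc_domains, foci, background_a, background_b,
                     seed = seed)
  })
}

#' Simulate a two-channel nucleus
#'
#' Generates the damage channel (A) and the chromatin channel (B) of a
#' synthetic nucleus from a [two_channel_spec()], with full ground truth
#' for classifier-recovery experiments.
#'
#' @param spec a [two_channel_spec()].
#' @return A list of class `two_channel_sim` with elements
#'   `channel_a`, `channel_b` (localization tables), `labels_a` (integer
#'   focus index per channel-A event, 0 for background), `foci` (the
#'   ground-truth focus table including `hc_associated`), `hc_domains`,
#'   `field` and `seed`.
#' @examples
#' sim <- simulate_two_channel(random_two_channel_spec(seed = 7))
#' table(sim$foci$hc_associated)
#' @export
simulate_two_channel <- function(spec) {
  stopifnot(inherits(spec, "two_channel_spec"))
  field <- spec$field
  out <- withr::with_seed(spec$seed, {
    # channel B: domains then background
    bxy <- matrix(numeric(), 0, 2)
    for (i in seq_len(nrow(spec$hc_domains))) {
      d <- spec$hc_domains[i, ]
      bxy <- rbind(bxy, cbind(d$x_nm, d$y_nm)[rep(1, d$n_points), ,
                                              drop = FALSE] +
                     rdisc(d$n_points, d$radius_nm))
    }
    bxy <- rbind(bxy, runif_field(spec$background_b, field))
    # channel A: foci then background
    axy <- matrix(numeric(), 0, 2)
    labels_a <- integer()
    for (i in seq_len(nrow(spec$foci))) {
      f <- spec$foci[i, ]
      axy <- rbind(axy, cbind(f$x_nm, f$y_nm)[rep(1, f$n_points), ,
                                              drop = FALSE] +
                     rdisc(f$n_points, f$radius_nm))
      labels_a <- c(labels_a, rep(i, f$n_points))
    }
    axy <- rbind(axy, runif_field(spec$background_a, field))
    labels_a <- c(labels_a, rep(0L, spec$background_a))
    list(axy = axy, bxy = bxy, labels_a = labels_a)
  })
  structure(list(
    channel_a = localization_table(seq_len(nrow(out$axy)), out$axy[, 1],
                                   out$axy[, 2], channel = "A",
                                   metadata = list(field = field)),
    channel_b = localization_table(seq_len(nrow(out$bxy)), out$bxy[, 1],
                                   out$bxy[, 2], channel = "B",
                                   metadata = list(field = field)),
    labels_a = out$labels_a, foci = spec$foci,
    hc_domains = spec$hc_domains, field = field, seed = spec$seed),
    class = "two_channel_sim")
}
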