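# Seeded generators of terrain fixtures with known drainage structure and
# of synthetic field-plot observations.  Every downstream module is tested
# against these, so the generators are deliberately simple, deterministic
# functions of (spec, seed).

#' Specify a synthetic DEM fixture
#'
#' @param kind One of `"inclined_plane"`, `"v_valley"`, `"gaussian_hill"`,
#'   `"pitted_surface"`, `"composite_landscape"`.
#' @param nrows,ncols Grid dimensions.
#' @param cell_size Cell size in metres (default 2, matching a national
#'   LiDAR elevation model).
#' @param seed Integer seed; the same spec and seed give a bit-identical DEM.
#' @param ... Kind-specific parameters: `gradient` (rise/run, inclined
#'   plane and regional tilt), `valley_depth` (m), `hill_amplitude` and
#'   `hill_width` (m), `n_pits` and `pit_depth` (m), `n_bumps` and
#'   `bump_amplitude` (m) for the composite landscape.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("inclined_plane", "v_valley", "gaussian_hill",
                                  "pitted_surface", "composite_landscape"),
                         nrows, ncols, cell_size = 2, seed = 1L, ...) {
  kind <- match.arg(kind)
  if (nrows < 1 || ncols < 1) stop("nrows and ncols must be positive")
  pars <- list(...)
  defaults <- list(gradient = 0.05, valley_depth = 10, hill_amplitude = 20,
                   hill_width = NULL, n_pits = 3, pit_depth = 1,
                   n_bumps = 40, bump_amplitude = 6)
  for (nm in names(defaults))
    if (is.null(pars[[nm]])) pars[[nm]] <- defaults[[nm]]
  structure(list(kind = kind, nrows = as.integer(nrows),
                 ncols = as.integer(ncols), cell_size = cell_size,
                 seed = as.integer(seed), parameters = pars),
            class = "fixture_spec")
}

#' Generate a synthetic DEM
#'
#' Deterministic terrain fixtures emulating elements of a glaciated boreal
#' landscape:
#' \describe{
#'   \item{inclined_plane}{uniform eastward gradient; already fully drained.}
#'   \item{v_valley}{two planar hillslopes meeting in a south-draining
#'     thalweg along the central column.}
#'   \item{gaussian_hill}{a single smooth hill on a flat plain.}
#'   \item{pitted_surface}{an inclined plane with exactly `n_pits`
#'     single-cell closed depressions at seeded interior locations.}
#'   \item{composite_landscape}{seeded smooth Gaussian bumps and hollows
#'     superimposed on a regional tilt, producing hillslopes, valleys,
#'     closed depressions and near-flats.}
#' }
#'
#' @param spec A [fixture_spec].
#' @return A [raster_grid] of elevations in metres.
#' @export
make_dem <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop("spec must be a fixture_spec")
  nr <- spec$nrows; nc <- spec$ncols; cs <- spec$cell_size
  p <- spec$parameters
  xs <- (seq_len(nc) - 0.5) * cs            # distance east of west edge
  ys <- (seq_len(nr) - 0.5) * cs            # distance south of north edge
  z <- switch(spec$kind,
    inclined_plane = {
      # rises to the east with the given gradient; drains west
      matrix(rep(p$gradient * xs, each = nr), nr, nc)
    },
    v_valley = {
      mid <- (nc / 2) * cs
      side <- abs(matrix(rep(xs, each = nr), nr, nc) - mid)
      # valley floor dips southward so the thalweg drains to the south edge
      thalweg <- matrix(rep(rev(ys), times = nc) * 0.01, nr, nc)
      side * (p$valley_depth / mid) + thalweg
    },
    gaussian_hill = {
      w <- if (is.null(p$hill_width)) min(nr, nc) * cs / 6 else p$hill_width
      cx <- nc * cs / 2; cy <- nr * cs / 2
      dx2 <- (matrix(rep(xs, each = nr), nr, nc) - cx)^2
      dy2 <- (matrix(rep(ys, times = nc), nr, nc) - cy)^2
      p$hill_amplitude * exp(-(dx2 + dy2) / (2 * w^2))
    },
    pitted_surface = {
      base <- matrix(rep(p$gradient * xs, each = nr), nr, nc)
      set.seed(spec$seed)
      if (nr < 5 || nc < 5) stop("pitted_surface needs at least a 5x5 grid")
      # sample interior, non-adjacent pit locations
      taken <- matrix(FALSE, nr, nc)
      placed <- 0L
      while (placed < p$n_pits) {
        r <- sample(3:(nr - 2), 1L); c <- sample(3:(nc - 2), 1L)
        if (any(taken[max(1, r - 2):min(nr, r + 2),
                      max(1, c - 2):min(nc, c + 2)])) next
        base[r, c] <- base[r, c] - p$pit_depth
        taken[r, c] <- TRUE
        placed <- placed + 1L
      }
      base
    },
    composite_landscape = {
      set.seed(spec$seed)
      tilt <- matrix(rep(p$gradient * xs, each = nr), nr, nc)
      X <- matrix(rep(xs, each = nr), nr, nc)
      Y <- matrix(rep(ys, times = nc), nr, nc)
      z <- tilt
      ext <- max(nr, nc) * cs
      for (i in seq_len(p$n_bumps)) {
        bx <- runif(1, 0, nc * cs); by <- runif(1, 0, nr * cs)
        amp <- rnorm(1, 0, p$bump_amplitude)
        w <- runif(1, ext / 30, ext / 8)
        z <- z + amp * exp(-((X - bx)^2 + (Y - by)^2) / (2 * w^2))
      }
      z
    })
  raster_grid(z, cs, crs_tag = "synthetic-metric")
}

#' Specify synthetic soil-moisture plots
#'
#' Plot labels follow a logistic model on the true cartographic
#' depth-to-water: `P(wet) = plogis(beta0 + beta1 * DTW)` with `beta1 < 0`
#' (wetter close to surface water).  Plot positions are cell centres
#' perturbed by Gaussian jitter emulating GPS error of field plots.
#'
#' @param n_plots Number of plots.
#' @param beta0,beta1 Logistic intercept and slope (per metre of DTW);
#'   `beta1` must be negative.  The defaults (2.2, -0.6) put the 50 %
#'   crossing near 3.7 m DTW and reproduce a ~40 % wet prevalence on the
#'   [demo_landscape()], the dry/wet split observed in national inventory
#'   plots.
#' @param jitter_sd Positional jitter standard deviation in metres
#'   (default 7.5, the midpoint of a 5-10 m GPS error band).
#' @param seed Integer seed.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(n_plots, beta0 = 2.2, beta1 = -0.6, jitter_sd = 7.5,
                      seed = 1L) {
  if (beta1 >= 0) stop("beta1 must be negative: wetness decreases with depth-to-water")
  if (n_plots < 1) stop("n_plots must be positive")
  structure(list(n_plots = as.integer(n_plots), beta0 = beta0, beta1 = beta1,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "plot_spec")
}

#' The standard demonstration landscape
#'
#' A 600 x 600 cell (1.2 x 1.2 km at 2 m) composite landscape — 80 smooth
#' seeded bumps and hollows of ~8 m amplitude on a 5 % regional tilt —
#' large enough (144 ha) that every stream initiation threshold up to
#' 30 ha produces a channel network.  This is the fixture used by the
#' worked examples and the end-to-end validation runs.
#'
#' @param seed Integer seed (default 42).
#' @param nrows,ncols Grid dimensions.
#' @return A [raster_grid] DEM.
#' @export
demo_landscape <- function(seed = 42L, nrows = 600, ncols = 600) {
  make_dem(fixture_spec("composite_landscape", nrows, ncols, cell_size = 2,
                        seed = seed, n_bumps = 80, bump_amplitude = 8))
}

# Five soil-moisture classes in increasing-wetness order with the marginal
# frequencies observed across a national forest inventory.
MOISTURE_CLASSES <- c("dry", "mesic", "mesic_moist", "moist", "wet")
MOISTURE_MARGINALS <- c(dry = 0.06, mesic = 0.54, mesic_moist = 0.27,
                        moist = 0.10, wet = 0.03)

#' Generate synthetic field plots from a true depth-to-water surface
#'
#' Draws plot locations uniformly over the grid (cell centres plus jitter),
#' evaluates the logistic wet-probability at the jittered location, and
#' draws the binary label Bernoulli from it.  The five-class soil-moisture
#' field is then assigned within each binary group by ranking the latent
#' probability, with group-conditional class frequencies renormalized from
#' the national marginals (6/54/27/10/3 % for dry/mesic/mesic-moist/moist/
#' wet), so that the binary recode of the five classes always reproduces
#' the drawn label and the class marginals approximate the national ones
#' when the wet fraction is near 40 %.
#'
#' @param spec A [plot_spec].
#' @param dtw_true A [raster_grid] of true depth-to-water values (m).
#' @return A `data.frame` with `plot_id`, `x`, `y`, `moisture_class`,
#'   `binary_label`.
#' @export
make_plots <- function(spec, dtw_true) {
  if (!inherits(spec, "plot_spec")) stop("spec must be a plot_spec")
  stopifnot_raster(dtw_true, "dtw_true")
  set.seed(spec$seed)
  g <- dtw_true
  nr <- nrow(g$values); nc <- ncol(g$values)
  n <- spec$n_plots
  # rejection-sample locations whose jittered position has a valid DTW
  x <- numeric(0); y <- numeric(0); p <- numeric(0)
  while (length(x) < n) {
    m <- (n - length(x)) * 2L + 10L
    r <- sample.int(nr, m, replace = TRUE)
    c <- sample.int(nc, m, replace = TRUE)
    px <- g$origin_x + (c - 0.5) * g$cell_size + rnorm(m, 0, spec$jitter_sd)
    py <- g$origin_y - (r - 0.5) * g$cell_size + rnorm(m, 0, spec$jitter_sd)
    cell <- rg_cell_of(g, px, py)
    ok <- !is.na(cell$row)
    dtw <- rep(NA_real_, m)
    dtw[ok] <- g$values[cbind(cell$row[ok], cell$col[ok])]
    keep <- !is.na(dtw)
    x <- c(x, px[keep]); y <- c(y, py[keep])
    p <- c(p, plogis(spec$beta0 + spec$beta1 * dtw[keep]))
  }
  x <- x[seq_len(n)]; y <- y[seq_len(n)]; p <- p[seq_len(n)]
  wet <- rbinom(n, 1L, p) == 1L

  # five-class assignment: within each binary group, wetter latent p maps to
  # wetter classes; conditional frequencies renormalized from the marginals
  cls <- character(n)
  assign_classes <- function(idx, classes, freq) {
    if (length(idx) == 0L) return()
    freq <- freq / sum(freq)
    counts <- diff(round(cumsum(c(0, freq)) * length(idx)))
    ord <- idx[order(p[idx])]        # driest (lowest p) first
    cls[ord] <<- rep(classes, counts)
  }
  assign_classes(which(!wet), c("dry", "mesic"), MOISTURE_MARGINALS[1:2])
  assign_classes(which(wet), c("mesic_moist", "moist", "wet"),
                 MOISTURE_MARGINALS[3:5])
  data.frame(plot_id = seq_len(n), x = x, y = y,
             moisture_class = factor(cls, levels = MOISTURE_CLASSES),
             binary_label = factor(ifelse(wet, "wet", "dry"),
                                   levels = c("dry", "wet")),
             stringsAsFactors = FALSE)
}
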