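# Quasi-static 2D electrostatics of a charged larva over interdigital comb
# electrodes: finite-difference Laplace solve, induced-charge integration,
# and the load-voltage waveform of one bend-stretch cycle.

EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Interdigital comb electrode geometry
#'
#' Teeth of width `tooth_width` separated by `gap_width`, alternating between
#' the grounded "base" comb and the "counter" comb that feeds the load. All
#' in-plane lengths are in micrometres. The 100 nm SiO2 isolation film is far
#' below the feature scale and is ignored in the potential solve.
#'
#' @param tooth_width tooth width in um (default 80).
#' @param gap_width gap between teeth in um (default 20).
#' @param n_teeth number of teeth in the modeled domain (6.5 for the
#'   symmetric half-domain; the physical device has 60).
#' @param insulation_thickness SiO2 film thickness in nm (documented, unused
#'   in the solve).
#' @param out_of_plane_depth depth used to scale the 2D (per-unit-depth)
#'   solution to coulombs, in mm; default 0.2 (the larval diameter).
#' @return a `comb_geometry` list.
#' @export
comb_geometry <- function(tooth_width = 80, gap_width = 20, n_teeth = 6.5,
                          insulation_thickness = 100,
                          out_of_plane_depth = 0.2) {
  if (tooth_width <= 0 || gap_width <= 0) {
    stop("`tooth_width` and `gap_width` must be positive", call. = FALSE)
  }
  structure(list(tooth_width = tooth_width, gap_width = gap_width,
                 n_teeth = n_teeth,
                 insulation_thickness = insulation_thickness,
                 out_of_plane_depth = out_of_plane_depth),
            class = "comb_geometry")
}

#' Larval body for the forward model
#'
#' The larva is idealized as a 2D rectangle whose length oscillates with the
#' bend–stretch cycle; the measured zeta potential is applied as a Dirichlet
#' surface potential on its outline (the body interior is excluded from the
#' dielectric).
#'
#' @param length_min,length_max length excursion in um (defaults 80 and 600).
#' @param height body height in um (default 100).
#' @param surface_potential effective surface potential in volts
#'   (default -21e-3, i.e. -21 mV).
#' @param clearance gap between body underside and the electrode plane in um
#'   (default 10).
#' @return a `larva_body` list.
#' @export
larva_body <- function(length_min = 80, length_max = 600, height = 100,
                       surface_potential = -21e-3, clearance = 10) {
  if (height <= 0) stop("`height` must be positive", call. = FALSE)
  if (length_min <= 0 || length_max <= length_min) {
    stop("need 0 < length_min < length_max", call. = FALSE)
  }
  structure(list(length_min = length_min, length_max = length_max,
                 height = height, surface_potential = surface_potential,
                 clearance = clearance),
            class = "larva_body")
}

#' Bend–stretch kinematics
#'
#' Triangular length-vs-time between the body's length extremes at
#' `cycle_frequency`, i.e. constant edge speed
#' `(length_max - length_min) * 2 * cycle_frequency` (2.08 mm/s at the
#' defaults).
#'
#' @param cycle_frequency bend–stretch rate in Hz (default 2).
#' @param waveform only `"triangular"` is implemented.
#' @return a `motion_kinematics` list.
#' @export
motion_kinematics <- function(cycle_frequency = 2, waveform = "triangular") {
  if (cycle_frequency <= 0) stop("`cycle_frequency` must be positive", call. = FALSE)
  if (!identical(waveform, "triangular")) {
    stop("only triangular kinematics are implemented", call. = FALSE)
  }
  structure(list(cycle_frequency = cycle_frequency, waveform = waveform),
            class = "motion_kinematics")
}

#' Mean edge speed of the triangular cycle
#' @param kin a [motion_kinematics()].
#' @param larva a [larva_body()].
#' @return total length change rate in mm/s.
#' @export
edge_speed <- function(kin, larva) {
  (larva$length_max - larva$length_min) * 2 * kin$cycle_frequency * 1e-3
}

#' Instantaneous body length under triangular kinematics
#' @param t times in s.
#' @param kin a [motion_kinematics()].
#' @param larva a [larva_body()].
#' @return body length in um at each `t` (starts at `length_min`, growing).
#' @export
triangular_length <- function(t, kin, larva) {
  phase <- (t * kin$cycle_frequency) %% 1
  tri <- ifelse(phase < 0.5, 2 * phase, 2 * (1 - phase))
  larva$length_min + (larva$length_max - larva$length_min) * tri
}

#' Simulation domain
#'
#' Rectangular water-filled domain above the electrode plane. With
#' `symmetry = TRUE` the left edge is a mirror plane (zero normal flux): the
#' domain models half of a symmetric larva, and induced charges are doubled.
#' Outer edges are zero-flux; electrodes and the body outline are Dirichlet.
#'
#' @param width,height domain size in um (defaults 680 x 130).
#' @param grid_spacing FD grid spacing in um; must resolve the comb gap with
#'   at least 4 cells (default 2.5).
#' @param permittivity_water relative permittivity of the medium (default 80).
#' @param symmetry mirror the domain at the left edge (default TRUE).
#' @return a `sim_domain` list.
#' @export
sim_domain <- function(width = 680, height = 130, grid_spacing = 2.5,
                       permittivity_water = 80, symmetry = TRUE) {
  if (grid_spacing <= 0) stop("`grid_spacing` must be positive", call. = FALSE)
  structure(list(width = width, height = height, grid_spacing = grid_spacing,
                 permittivity_water = permittivity_water, symmetry = symmetry),
            class = "sim_domain")
}

#' Load circuit
#' @param load_resistance load resistance in ohms (default 150, the measured
#'   device resistance).
#' @return a `circuit` list.
#' @export
circuit <- function(load_resistance = 150) {
  if (load_resistance <= 0) stop("`load_resistance` must be positive", call. = FALSE)
  structure(list(load_resistance = load_resistance), class = "circuit")
}

# Solve Laplace's equation on a uniform grid given a Dirichlet mask.
#
# `bc` is an (ny x nx) matrix: NA marks unknown nodes, finite values are
# Dirichlet potentials. Outer boundaries are zero normal flux (mirror)
# wherever no Dirichlet value is set. Direct sparse solve of the SPD 5-point
# system. Returns the full potential matrix.
#' Finite-difference Laplace solve on a Dirichlet mask
#'
#' Low-level solver used by [solve_potential()] and by degenerate-geometry
#' oracle checks. Row index = y (row 1 at the bottom), column index = x.
#'
#' @param bc matrix of Dirichlet values with `NA` for unknown nodes; at least
#'   one finite entry is required.
#' @param h grid spacing (any consistent length unit).
#' @return matrix of potentials of the same shape as `bc`.
#' @export
solve_laplace_grid <- function(bc, h = 1) {
  ny <- nrow(bc); nx <- ncol(bc)
  known <- is.finite(bc)
  if (!any(known)) stop("at least one Dirichlet node is required", call. = FALSE)
  unknown <- !known
  nunk <- sum(unknown)
  if (nunk == 0L) return(bc)
  idx <- matrix(0L, ny, nx)
  idx[unknown] <- seq_len(nunk)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_cnt <- numeric(nunk)
  b <- numeric(nunk)

  shift <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  ur <- row(bc)[unknown]; uc <- col(bc)[unknown]
  uid <- idx[unknown]
  for (s in shift) {
    nr <- ur + s[1]; nc <- uc + s[2]
    inside <- nr >= 1L & nr <= ny & nc >= 1L & nc <= nx
    lin <- (nc[inside] - 1L) * ny + nr[inside]
    nbr_known <- known[lin]
    # in-domain neighbours contribute to the diagonal; outside = mirror (skip)
    diag_cnt[uid[inside]] <- diag_cnt[uid[inside]] + 1
    # unknown neighbour -> off-diagonal entry
    src <- uid[inside][!nbr_known]
    dst <- idx[lin[!nbr_known]]
    ii <- c(ii, src); jj <- c(jj, dst); vv <- c(vv, rep(-1, length(src)))
    # known neighbour -> right-hand side
    b[uid[inside][nbr_known]] <- b[uid[inside][nbr_known]] + bc[lin[nbr_known]]
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nunk)), j = c(jj, seq_len(nunk)),
                            x = c(vv, diag_cnt), dims = c(nunk, nunk))
  phi_u <- as.numeric(Matrix::solve(A, b))
  out <- bc
  out[unknown] <- phi_u
  out
}

# Build the Dirichlet mask for a comb + larva configuration.
# Returns list(bc, electrode_id matrix (0 = none, k = tooth k), larva mask).
build_bc <- function(domain, comb, larva, larva_extent) {
  h <- domain$grid_spacing
  nx <- round(domain$width / h) + 1L
  ny <- round(domain$height / h) + 1L
  x <- (seq_len(nx) - 1L) * h
  y <- (seq_len(ny) - 1L) * h
  bc <- matrix(NA_real_, ny, nx)
  eid <- matrix(0L, ny, nx)

  period <- comb$tooth_width + comb$gap_width
  n_teeth <- ceiling(comb$n_teeth)
  for (k in seq_len(n_teeth)) {
    x0 <- (k - 1L) * period
    x1 <- min(x0 + comb$tooth_width, domain$width)
    if (x0 > domain$width) break
    cols <- which(x >= x0 - 1e-9 & x <= x1 + 1e-9)
    bc[1L, cols] <- 0
    eid[1L, cols] <- k
  }

  if (larva_extent > 0) {
    if (larva$clearance + larva$height > domain$height ||
        larva_extent > domain$width) {
      stop("larva does not fit inside the simulation domain", call. = FALSE)
    }
    rows <- which(y >= larva$clearance - 1e-9 &
                  y <= larva$clearance + larva$height + 1e-9)
    cols <- which(x <= larva_extent + 1e-9)
    bc[rows, cols] <- larva$surface_potential
  }
  lmask <- matrix(FALSE, ny, nx)
  if (larva_extent > 0) lmask[rows, cols] <- TRUE
  list(bc = bc, eid = eid, larva = lmask, h = h, x = x, y = y)
}

#' Solve the potential field for one body extent
#'
#' Discrete Laplace solution with the electrodes held at 0 V (short-circuit
#' approximation: the ohmic excursion across the 150 ohm load is micro- to
#' millivolt-scale, negligible against the boundary potentials) and the body
#' outline at its surface potential.
#'
#' @param domain a [sim_domain()].
#' @param comb a [comb_geometry()].
#' @param larva a [larva_body()].
#' @param larva_extent body extent in um measured from the left (mirror)
#'   edge; 0 means no larva present.
#' @return a `potential_field`: potential matrix `phi` (row 1 = electrode
#'   plane), node coordinates, electrode-id and body masks, and the inputs.
#' @export
solve_potential <- function(domain, comb, larva, larva_extent) {
  if (comb$gap_width / domain$grid_spacing < 4 - 1e-9) {
    stop("grid_spacing too coarse: the comb gap must span >= 4 cells", call. = FALSE)
  }
  g <- build_bc(domain, comb, larva, larva_extent)
  phi <- solve_laplace_grid(g$bc, g$h)
  structure(list(phi = phi, x = g$x, y = g$y, electrode_id = g$eid,
                 larva_mask = g$larva, h = g$h, domain = domain, comb = comb,
                 larva = larva, larva_extent = larva_extent),
            class = "potential_field")
}

# Discrete normal-flux sum (volts) out of a node set: sum over boundary edges
# of (phi_set - phi_neighbour). Multiplying by eps0*eps_r gives charge per
# unit depth; the discrete Gauss identity makes fluxes over all conductors
# cancel exactly.
flux_out_of <- function(phi, mask) {
  ny <- nrow(phi); nx <- ncol(phi)
  tot <- 0
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  mr <- row(phi)[mask]; mc <- col(phi)[mask]
  for (s in shifts) {
    nr <- mr + s[1]; nc <- mc + s[2]
    ok <- nr >= 1L & nr <= ny & nc >= 1L & nc <= nx
    lin_n <- (nc[ok] - 1L) * ny + nr[ok]
    lin_m <- (mc[ok] - 1L) * ny + mr[ok]
    outside_set <- !mask[lin_n]
    tot <- tot + sum(phi[lin_m[outside_set]] - phi[lin_n[outside_set]])
  }
  tot
}

#' Induced charge on one comb tooth
#'
#' Surface integral of the normal displacement field over the named tooth,
#' scaled by the out-of-plane depth (and doubled under mirror symmetry).
#' With the sign convention used, charge opposite to the (negative) body
#' charge appears as positive on the electrodes.
#'
#' @param field a `potential_field` from [solve_potential()].
#' @param comb the [comb_geometry()] used (for the depth scale).
#' @param electrode_id tooth index (1-based).
#' @return induced charge in coulombs.
#' @export
induced_charge <- function(field, comb = field$comb, electrode_id) {
  n_teeth <- max(field$electrode_id)
  if (electrode_id < 1 || electrode_id > n_teeth) {
    stop("`electrode_id` out of range 1..", n_teeth, call. = FALSE)
  }
  mask <- field$electrode_id == electrode_id
  # flux out of a 0 V electrode toward negative potentials is positive
  # (phi_e - phi_n > 0): charge on the electrode = +eps * flux_out
  q <- EPS0 * field$domain$permittivity_water * flux_out_of(field$phi, mask) *
    comb$out_of_plane_depth * 1e-3
  if (isTRUE(field$domain$symmetry)) q <- 2 * q
  q
}

#' Total induced charge on one comb
#'
#' Sums [induced_charge()] over alternate teeth. Odd teeth form the base
#' comb, even teeth the counter comb (the one feeding the load).
#'
#' @param field a `potential_field`.
#' @param which `"counter"`, `"base"` or `"all"`.
#' @return charge in coulombs.
#' @export
comb_charge <- function(field, which = c("counter", "base", "all")) {
  which <- match.arg(which)
  n_teeth <- max(field$electrode_id)
  ids <- switch(which,
                counter = seq(2L, n_teeth, by = 2L),
                base = seq(1L, n_teeth, by = 2L),
                all = seq_len(n_teeth))
  sum(vapply(ids, function(k) induced_charge(field, field$comb, k), 0))
}

#' Total charge on the body outline
#' @param field a `potential_field` with a body present.
#' @return charge in coulombs (negative for a negative surface potential).
#' @export
body_charge <- function(field) {
  if (!any(field$larva_mask)) return(0)
  q <- EPS0 * field$domain$permittivity_water *
    flux_out_of(field$phi, field$larva_mask) *
    field$comb$out_of_plane_depth * 1e-3
  if (isTRUE(field$domain$symmetry)) q <- 2 * q
  q
}

#' Simulate the load voltage over bend–stretch cycles
#'
#' Quasi-static chain: the body extent follows the triangular kinematics;
#' at each grid-resolved extent the Laplace problem is solved and the
#' counter-comb induced charge Q is integrated; the load current is
#' I = dQ/dt (central differences in extent times the constant edge speed,
#' signed by the motion direction) and the output voltage is
#' V = I * load_resistance.
#'
#' Because the problem is quasi-static, Q depends on extent alone: it is
#' evaluated once per grid-aligned extent and interpolated over the time
#' grid, which keeps the differentiation smooth and the cost at one sparse
#' solve per extent node.
#'
#' @param domain a [sim_domain()].
#' @param comb a [comb_geometry()].
#' @param larva a [larva_body()].
#' @param kin a [motion_kinematics()].
#' @param circ a [circuit()].
#' @param n_steps time samples per cycle (>= 20).
#' @param n_cycles number of cycles (default 1).
#' @return a [waveform()] sampled at `n_steps * cycle_frequency` Hz whose
#'   metadata records the voltage amplitude (max |V|), the charge-vs-extent
#'   table and the model parameters.
#' @export
simulate_cycle <- function(domain = sim_domain(), comb = comb_geometry(),
                           larva = larva_body(), kin = motion_kinematics(),
                           circ = circuit(), n_steps = 40L, n_cycles = 1L) {
  if (n_steps < 20L) stop("`n_steps` must be >= 20 per cycle", call. = FALSE)
  h <- domain$grid_spacing
  half <- if (isTRUE(domain$symmetry)) 2 else 1
  ext_min <- larva$length_min / half
  ext_max <- larva$length_max / half
  ext_nodes <- seq(floor(ext_min / h), ceiling(ext_max / h)) * h
  ext_nodes <- ext_nodes[ext_nodes <= domain$width]
  q_nodes <- vapply(ext_nodes, function(e) {
    f <- solve_potential(domain, comb, larva, e)
    comb_charge(f, "counter")
  }, 0)
  # dQ/d(extent), C/um, central differences on the extent grid
  dq <- numeric(length(ext_nodes))
  dq[1] <- (q_nodes[2] - q_nodes[1]) / h
  nn <- length(ext_nodes)
  dq[nn] <- (q_nodes[nn] - q_nodes[nn - 1]) / h
  if (nn > 2) dq[2:(nn - 1)] <- (q_nodes[3:nn] - q_nodes[1:(nn - 2)]) / (2 * h)

  fs <- n_steps * kin$cycle_frequency
  t <- (seq_len(n_steps * n_cycles) - 1) / fs
  ext_t <- triangular_length(t, kin, larva) / half
  phase <- (t * kin$cycle_frequency) %% 1
  dirn <- ifelse(phase < 0.5, 1, -1)       # stretching vs shrinking
  v_edge <- (ext_max - ext_min) * 2 * kin$cycle_frequency  # um/s (one edge)
  dqdt <- stats::approx(ext_nodes, dq, xout = pmin(pmax(ext_t, ext_nodes[1]),
                                                   ext_nodes[nn]))$y *
    dirn * v_edge
  volts <- dqdt * circ$load_resistance
  waveform(volts, fs,
           metadata = list(kind = "simulated",
                           amplitude_V = max(abs(volts)),
                           charge_vs_extent = data.frame(extent_um = ext_nodes,
                                                         q_counter_C = q_nodes),
                           surface_potential = larva$surface_potential,
                           grid_spacing = h,
                           load_resistance = circ$load_resistance))
}

#' Ohm's-law current from a voltage amplitude
#' @param voltage_amplitude voltage amplitude in V (>= 0).
#' @param circ a [circuit()].
#' @return current in A. `ohmic_current(0.11e-3, circuit(150))` is the
#'   733 nA worked example (printed as 730 nA).
#' @export
ohmic_current <- function(voltage_amplitude, circ = circuit()) {
  if (voltage_amplitude < 0) stop("`voltage_amplitude` must be >= 0", call. = FALSE)
  voltage_amplitude / circ$load_resistance
}

#' Electrical power from voltage and current amplitudes
#' @param voltage_amplitude voltage in V (>= 0).
#' @param current_amplitude current in A (>= 0).
#' @return power in W (0.11 mV x 730 nA gives the 80 pW worked example).
#' @export
electrical_power <- function(voltage_amplitude, current_amplitude) {
  if (voltage_amplitude < 0 || current_amplitude < 0) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  voltage_amplitude * current_amplitude
}

#' Export a potential field as a plain-text matrix grid
#' @param field a `potential_field`.
#' @param path output path (whitespace-separated matrix, row 1 = electrode
#'   plane).
#' @return `path`, invisibly.
#' @export
write_potential_field <- function(field, path) {
  utils::write.table(field$phi, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
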