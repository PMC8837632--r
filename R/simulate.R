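#' Simulation parameters for synthetic synovium volumes
#'
#' Defines the generative model for a multi-section ST volume emulating an
#' inflamed synovial biopsy: spots on a jittered grid per section, one or
#' more dense lymphoid aggregates (TLO cores) with radially arranged
#' surrounding zones, per-spot cell-type mixtures drawn from zone-specific
#' Dirichlet profiles, negative-binomial count noise, lognormal sequencing
#' depth, and a cell table whose density peaks in the TLO cores.
#'
#' Defaults emulate the study conditions: 3 consecutive sections of roughly
#' 650 spots each (a 1000-2000-feature array, partially covered by tissue),
#' one central aggregate whose radial zones (core, two rings, lining) tile
#' the tissue, 5 reference cell types, and moderate ST overdispersion.
#'
#' @param n_sections number of serial sections.
#' @param spots_per_section spots per section.
#' @param n_genes genes in the reference and the count matrix.
#' @param n_cell_types number of reference cell types (>= 2). The first five
#'   take the roles B cell, T cell, fibroblast, macrophage, dendritic cell;
#'   further types are generic low-abundance populations.
#' @param tlo_centers list of numeric `c(x, y, radius)` aggregates, in array
#'   units on the `[0, extent]` square.
#' @param ring_multipliers radii of the two surrounding rings as multiples of
#'   the core radius.
#' @param extent side length of the array in array units.
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size); `Inf` gives Poisson counts.
#' @param depth_mean mean per-spot sequencing depth (total counts).
#' @param depth_sdlog lognormal sd of depth on the log scale.
#' @param marker_logfc natural-log fold change of each cell type's marker
#'   block over background.
#' @param markers_per_type genes in each type's marker block.
#' @param mixture_concentration Dirichlet concentration around the zone
#'   profile (larger = less spot-to-spot mixture variability).
#' @param density_means expected cells per spot window, named by zone.
#' @param seed integer RNG seed; all simulator randomness derives from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_sections = 3, spots_per_section = 650,
                       n_genes = 1000, n_cell_types = 6,
                       tlo_centers = list(c(50, 50, 20)),
                       ring_multipliers = c(1.6, 2.3),
                       extent = 100,
                       nb_dispersion = 5, depth_mean = 3000,
                       depth_sdlog = 0.3,
                       marker_logfc = 2, markers_per_type = 25,
                       mixture_concentration = 150,
                       density_means = c(TLO_core = 45, ring1 = 25,
                                         ring2 = 15, lining = 10),
                       seed = 1) {
  stopifnot(n_sections >= 1, spots_per_section >= 4, n_genes >= 1,
            n_cell_types >= 2, nb_dispersion > 0, depth_mean > 0,
            markers_per_type >= 1, length(ring_multipliers) == 2,
            all(diff(c(1, ring_multipliers)) > 0))
  for (ctr in tlo_centers) {
    stopifnot(length(ctr) == 3)
    if (ctr[3] <= 0 || ctr[1] - ctr[3] < 0 || ctr[1] + ctr[3] > extent ||
        ctr[2] - ctr[3] < 0 || ctr[2] + ctr[3] > extent)
      stop_spatlo("TLO core radius must fit inside the array extent",
                  "spatlo_parameter_error")
  }
  if (n_cell_types * markers_per_type > n_genes)
    stop_spatlo("n_genes too small to host disjoint marker blocks",
                "spatlo_parameter_error")
  structure(as.list(environment()), class = "sim_params")
}

# run code with a private RNG stream, restoring the caller's state
with_sim_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

cell_type_roles <- function(n) {
  # the fibroblast compartment is split into THY1+ sublining ("Fibroblast")
  # and CD55+ lining fibroblasts, mirroring synovial scRNA-seq references
  roles <- c("B_cell", "T_cell", "Fibroblast", "Macrophage", "DC",
             "Lining_fibroblast")
  if (n <= 6) roles[seq_len(n)] else c(roles, paste0("Type", seq.int(7, n)))
}

# zone composition profiles over cell-type roles; rows normalized later.
# Each radial zone has a distinct dominant population: lymphocyte-rich
# cores, a macrophage-rich inner ring, a sublining-fibroblast outer ring,
# and a CD55+ lining layer. Seronegative cores are fibroblast/DC-driven.
zone_role_weights <- function(group) {
  if (group == "seropositive") {
    list(
      TLO_core = c(B_cell = 0.34, T_cell = 0.34, Fibroblast = 0.08,
                   Macrophage = 0.10, DC = 0.10, Lining_fibroblast = 0.04),
      ring1    = c(B_cell = 0.05, T_cell = 0.05, Fibroblast = 0.26,
                   Macrophage = 0.48, DC = 0.12, Lining_fibroblast = 0.04),
      ring2    = c(B_cell = 0.04, T_cell = 0.04, Fibroblast = 0.50,
                   Macrophage = 0.16, DC = 0.22, Lining_fibroblast = 0.04),
      lining   = c(B_cell = 0.04, T_cell = 0.04, Fibroblast = 0.18,
                   Macrophage = 0.08, DC = 0.04, Lining_fibroblast = 0.62))
  } else {
    list(
      TLO_core = c(B_cell = 0.05, T_cell = 0.05, Fibroblast = 0.34,
                   Macrophage = 0.14, DC = 0.36, Lining_fibroblast = 0.06),
      ring1    = c(B_cell = 0.05, T_cell = 0.05, Fibroblast = 0.28,
                   Macrophage = 0.44, DC = 0.14, Lining_fibroblast = 0.04),
      ring2    = c(B_cell = 0.04, T_cell = 0.04, Fibroblast = 0.50,
                   Macrophage = 0.16, DC = 0.22, Lining_fibroblast = 0.04),
      lining   = c(B_cell = 0.04, T_cell = 0.04, Fibroblast = 0.18,
                   Macrophage = 0.08, DC = 0.04, Lining_fibroblast = 0.62))
  }
}

zone_profiles <- function(params, group = "seropositive") {
  roles <- cell_type_roles(params$n_cell_types)
  w <- zone_role_weights(group)
  prof <- t(vapply(w, function(zw) {
    v <- zw[roles]
    v[is.na(v)] <- 0.04  # generic extra types: small share everywhere
    names(v) <- paste0("CT", seq_along(roles))
    v / sum(v)
  }, numeric(length(roles))))
  prof
}

#' Build a synthetic cell-type marker reference
#'
#' Each cell type receives a disjoint block of marker genes expressed
#' `exp(marker_logfc)`-fold over a shared lognormal background; the
#' signature matrix rows are normalized to sum to one (relative expression).
#' The returned signature set applies the same marker filter as
#' [read_signatures()] (avg_logfc > 1, FDR < 5%, top 200).
#'
#' @param params a [sim_params] object.
#' @return list with elements `signatures` (a [signature_set]) and
#'   `signature_matrix` (cell types x genes, rows summing to 1).
#' @export
make_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_sim_seed(params$seed + 1L, {
    L <- params$n_cell_types
    G <- params$n_genes
    genes <- sprintf("G%04d", seq_len(G))
    baseline <- rlnorm(G, meanlog = 0, sdlog = 1)
    B <- matrix(rep(baseline, each = L), nrow = L,
                dimnames = list(paste0("CT", seq_len(L)), genes))
    k <- params$markers_per_type
    marker_rows <- list()
    for (l in seq_len(L)) {
      block <- ((l - 1) * k + 1):(l * k)
      B[l, block] <- B[l, block] * exp(params$marker_logfc)
      marker_rows[[l]] <- data.frame(
        cell_type = paste0("CT", l), gene = genes[block],
        avg_logfc = params$marker_logfc, fdr = 1e-6)
    }
    B <- B / rowSums(B)
    tab <- do.call(rbind, marker_rows)
    keep <- tab$avg_logfc > 1 & tab$fdr < 0.05
    sig <- if (any(keep)) {
      s <- signature_set(tab[keep, , drop = FALSE])
      # retain filtered-out types as empty marker lists
      for (ct in setdiff(unique(tab$cell_type), names(s)))
        s[[ct]] <- tab[0, c("gene", "avg_logfc", "fdr")]
      s[paste0("CT", seq_len(L))]
    } else {
      structure(setNames(rep(list(tab[0, c("gene", "avg_logfc", "fdr")]), L),
                         paste0("CT", seq_len(L))), class = "signature_set")
    }
    class(sig) <- "signature_set"
    list(signatures = sig, signature_matrix = B)
  })
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

spot_zones <- function(x, y, params) {
  if (length(params$tlo_centers) == 0)
    return(rep("lining", length(x)))
  d <- Reduce(pmin, lapply(params$tlo_centers, function(ctr)
    sqrt((x - ctr[1])^2 + (y - ctr[2])^2) / ctr[3]))
  zone <- rep("lining", length(x))
  zone[d <= params$ring_multipliers[2]] <- "ring2"
  zone[d <= params$ring_multipliers[1]] <- "ring1"
  zone[d <= 1] <- "TLO_core"
  zone
}

#' Simulate a multi-section ST volume with known ground truth
#'
#' Lays spots on a jittered grid per section, assigns each spot a radial
#' zone (TLO core, two rings, synovial lining) from its distance to the
#' nearest aggregate center, draws a per-spot cell-type mixture from the
#' zone's Dirichlet profile, sets expected expression to
#' `depth * (proportions %*% signature_matrix)` and draws negative-binomial
#' counts. A cell table is generated alongside: expected cell counts are
#' highest in the cores, and core cells are small (lymphocytes) while
#' peripheral cells are large (fibroblasts, macrophages).
#'
#' @param params a [sim_params] object.
#' @param signature_matrix cell types x genes matrix from [make_reference()].
#' @param group `"seropositive"` (lymphocyte-dominated cores) or
#'   `"seronegative"` (fibroblast/DC-dominated cores).
#' @return list with elements `counts` ([spot_matrix], raw), `spots`
#'   (spot table with barcode, x, y, section_id, z, annotation), `truth`
#'   (per-spot true zone, group, expected density, true mixture columns
#'   `prop_<type>`), and `cells` (cell table: x, y, area, section_id).
#'   Spot windows are one grid pitch wide; cell coordinates share the spot
#'   frame, and `attr(cells, "window")` records the matching aggregation
#'   window size.
#' @export
simulate_volume <- function(params, signature_matrix,
                            group = c("seropositive", "seronegative")) {
  stopifnot(inherits(params, "sim_params"))
  group <- match.arg(group)
  L <- nrow(signature_matrix)
  with_sim_seed(params$seed, {
    prof <- zone_profiles(params, group)
    nx <- ceiling(sqrt(params$spots_per_section))
    pitch <- params$extent / nx
    spots_list <- list(); truth_list <- list(); cells_list <- list()
    counts_list <- list()
    for (s in seq_len(params$n_sections)) {
      grid <- expand.grid(ix = seq_len(nx), iy = seq_len(nx))
      take <- sort(sample.int(nrow(grid), params$spots_per_section))
      gx <- (grid$ix[take] - 0.5) * pitch
      gy <- (grid$iy[take] - 0.5) * pitch
      x <- gx + runif(length(take), -0.3, 0.3) * pitch
      y <- gy + runif(length(take), -0.3, 0.3) * pitch
      zone <- spot_zones(x, y, params)
      n <- length(x)
      barcode <- sprintf("S%02d_%04d", s, seq_len(n))
      section_id <- sprintf("sec%02d", s)
      depth <- rlnorm(n, meanlog = log(params$depth_mean) -
                        params$depth_sdlog^2 / 2, sdlog = params$depth_sdlog)
      props <- t(vapply(zone, function(z)
        rdirichlet_one(params$mixture_concentration * prof[z, ]),
        numeric(L)))
      mu <- depth * (props %*% signature_matrix)
      cnt <- if (is.infinite(params$nb_dispersion))
        matrix(rpois(length(mu), lambda = mu), nrow = n)
      else
        matrix(rnbinom(length(mu), size = params$nb_dispersion, mu = mu),
               nrow = n)
      dimnames(cnt) <- list(barcode, colnames(signature_matrix))
      dens_mean <- params$density_means[zone]
      n_cells <- rpois(n, dens_mean)
      idx <- rep.int(seq_len(n), n_cells)
      if (length(idx)) {
        cells_list[[s]] <- data.frame(
          x = x[idx] + runif(length(idx), -0.5, 0.5) * pitch,
          y = y[idx] + runif(length(idx), -0.5, 0.5) * pitch,
          area = ifelse(zone[idx] == "TLO_core",
                        rlnorm(length(idx), log(30), 0.2),
                        rlnorm(length(idx), log(80), 0.3)),
          section_id = section_id)
      }
      spots_list[[s]] <- data.frame(
        barcode = barcode, x = x, y = y, section_id = section_id,
        z = (s - 1) * 7,
        annotation = ifelse(zone == "TLO_core", "infiltrate", "other"))
      tr <- data.frame(barcode = barcode, section_id = section_id,
                       true_cluster = zone, group = group,
                       true_density = as.numeric(dens_mean))
      colnames(props) <- rownames(signature_matrix)
      tr <- cbind(tr, setNames(as.data.frame(props),
                               paste0("prop_", colnames(props))))
      truth_list[[s]] <- tr
      counts_list[[s]] <- cnt
    }
    counts <- do.call(rbind, counts_list)
    spots <- do.call(rbind, spots_list)
    truth <- do.call(rbind, truth_list)
    cells <- if (length(cells_list)) do.call(rbind, cells_list) else
      data.frame(x = numeric(), y = numeric(), area = numeric(),
                 section_id = character())
    rownames(spots) <- rownames(truth) <- rownames(cells) <- NULL
    attr(cells, "window") <- pitch
    list(counts = spot_matrix(counts, "raw"), spots = spots,
         truth = truth, cells = cells)
  })
}
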