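#' Reference 18-landmark wing template
#'
#' A fixed planar configuration emulating the classic mosquito-wing
#' digitization scheme: 12 points along the wing margin (base, costal edge,
#' tip, posterior margin) and 6 interior points at vein-junction-like
#' positions. Centered and scaled to unit centroid size; no two landmarks
#' are closer than 0.02.
#'
#' @return `18 x 2` coordinate matrix with unit centroid size
#' @export
default_wing_template <- function() {
  xy <- rbind(
    c(0.00,  0.00),  # 1  wing base
    c(0.15,  0.08),  # 2  costal margin
    c(0.35,  0.12),  # 3
    c(0.55,  0.13),  # 4
    c(0.75,  0.11),  # 5
    c(0.92,  0.06),  # 6
    c(1.00,  0.00),  # 7  wing tip
    c(0.90, -0.07),  # 8  posterior margin
    c(0.72, -0.12),  # 9
    c(0.52, -0.14),  # 10
    c(0.30, -0.12),  # 11
    c(0.12, -0.08),  # 12
    c(0.25,  0.03),  # 13 interior vein junctions
    c(0.42,  0.05),  # 14
    c(0.60,  0.04),  # 15
    c(0.45, -0.04),  # 16
    c(0.63, -0.05),  # 17
    c(0.80,  0.00))  # 18
  xy <- center_config(xy)
  xy / centroid_size(xy)
}

# Species design of the emulated study: abbreviation, genus, number of
# sampling sites, number of specimens.
study_species_table <- function() {
  data.frame(
    species = c("Ae_ann", "Ae_can", "Ae_cas", "Ae_cin", "Ae_com", "Ae_gen",
                "Ae_pun", "Ae_ross", "Ae_rust", "Ae_stic", "Ae_vex",
                "An_clav", "An_mess", "An_pb", "Cq_rich", "Cx_pip",
                "Cx_terr", "Cs_ann", "Cs_mors"),
    genus = c(rep("Aedes", 11), rep("Anopheles", 3), "Coquillettidia",
              rep("Culex", 2), rep("Culiseta", 2)),
    n_sites = c(13, 15, 6, 11, 12, 13, 13, 3, 12, 14, 16, 16, 13, 13, 11,
                5, 13, 19, 17),
    n_specimens = c(30, 30, 17, 30, 29, 24, 30, 14, 29, 30, 30, 30, 19, 30,
                    30, 18, 22, 30, 30),
    stringsAsFactors = FALSE)
}

#' Simulation design for synthetic wing-landmark datasets
#'
#' The defaults emulate the study design the generator stands in for: 19
#' mosquito species in 5 genera with the per-species specimen and
#' sampling-site counts of the original survey (502 specimens total), 18
#' landmarks per wing, and noise scales calibrated so the within-species
#' Procrustes variance is about 0.0012 shape units -- the magnitude
#' observed for real mosquito wings. Genus mean shapes are displaced from
#' the template at scale `2 * delta` per coordinate and species means from
#' their genus at scale `delta`, so genera separate more than species;
#' `delta = 8 * sigma_w` gives the strong interspecific signal regime.
#'
#' @param species character vector of species names
#' @param genus_map named character vector, species -> genus
#' @param n_per_species integer vector (recycled) of specimens per species
#' @param n_sites integer vector (recycled) of sampling sites per species
#' @param k number of landmarks (>= 4); 18 uses the wing template, other
#'   values use evenly spaced points on an ellipse
#' @param sigma_w within-species isotropic landmark noise, shape units
#' @param delta species-level mean displacement scale per coordinate
#' @param sigma_site shared per-(species, site) shape offset scale
#' @param size_median_range range of species median centroid sizes
#'   (arbitrary units, e.g. mm); species medians are log-spaced across it
#' @param size_cv within-species coefficient of variation of centroid size
#'   (lognormal)
#' @param beta allometry coefficient: shape displacement per unit
#'   log(CS / species median CS) along a common direction; 0 disables
#' @param sigma_obs observer digitization noise (shape units), used by
#'   [simulate_observer_replicates()]
#' @param merge_pair optional length-2 species names whose mean shapes are
#'   forced within `merge_distance` of each other (Procrustes distance)
#' @param merge_distance target mean-shape distance for `merge_pair`;
#'   default `sigma_w`
#' @return a `simulation_design` list
#' @export
simulation_design <- function(species = NULL, genus_map = NULL,
                              n_per_species = NULL, n_sites = NULL,
                              k = 18, sigma_w = 0.0055,
                              delta = 8 * sigma_w,
                              sigma_site = sigma_w / 2,
                              size_median_range = c(2.4, 4.4),
                              size_cv = 0.08, beta = 0.07,
                              sigma_obs = sigma_w / 2,
                              merge_pair = NULL, merge_distance = NULL) {
  tab <- study_species_table()
  if (is.null(species)) {
    species <- tab$species
    if (is.null(genus_map))
      genus_map <- stats::setNames(tab$genus, tab$species)
    if (is.null(n_per_species)) n_per_species <- tab$n_specimens
    if (is.null(n_sites)) n_sites <- tab$n_sites
  }
  if (is.null(genus_map))
    genus_map <- stats::setNames(rep("GenusA", length(species)), species)
  if (is.null(n_per_species)) n_per_species <- 20
  if (is.null(n_sites)) n_sites <- 3
  n_per_species <- stats::setNames(rep_len(n_per_species, length(species)),
                                   species)
  n_sites <- stats::setNames(rep_len(n_sites, length(species)), species)
  stopifnot(all(n_per_species >= 2), k >= 4, sigma_w >= 0, delta >= 0,
            sigma_site >= 0, sigma_obs >= 0, size_cv >= 0,
            all(species %in% names(genus_map)))
  if (!is.null(merge_pair)) {
    stopifnot(length(merge_pair) == 2, all(merge_pair %in% species))
    if (is.null(merge_distance)) merge_distance <- sigma_w
  }
  structure(list(species = species, genus_map = genus_map,
                 n_per_species = n_per_species, n_sites = n_sites, k = k,
                 sigma_w = sigma_w, delta = delta, sigma_site = sigma_site,
                 size_median_range = size_median_range, size_cv = size_cv,
                 beta = beta, sigma_obs = sigma_obs,
                 merge_pair = merge_pair, merge_distance = merge_distance),
            class = "simulation_design")
}

template_for_k <- function(k) {
  if (k == 18) return(default_wing_template())
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  xy <- cbind(cos(th), 0.4 * sin(th))
  xy <- center_config(xy)
  xy / centroid_size(xy)
}

normalize_shape <- function(m) {
  m <- center_config(m)
  m / centroid_size(m)
}

#' Simulate a landmark dataset with known ground truth
#'
#' Draws genus and species mean shapes around the wing template, then per
#' specimen adds a shared (species, site) offset, isotropic landmark noise,
#' and an optional allometric displacement proportional to the specimen's
#' log centroid size; finally each configuration is randomly rotated,
#' translated and scaled to its drawn centroid size, so that raw output
#' exercises the full superimposition pipeline. All randomness flows from
#' `seed`; identical seeds give bit-identical datasets.
#'
#' @param design a [simulation_design()]
#' @param seed integer seed
#' @return list with `dataset` (a [landmark_dataset()]) and `truth`
#'   (species mean shapes as a `k x 2 x n_species` array of unit-CS
#'   configurations, genus map, per-specimen true sizes, the design, seed)
#' @export
simulate_landmark_dataset <- function(design, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(seed, {
    k <- design$k
    tmpl <- template_for_k(k)
    genera <- unique(unname(design$genus_map[design$species]))
    genus_means <- lapply(genera, function(g)
      tmpl + matrix(stats::rnorm(2 * k, 0, 2 * design$delta), k, 2))
    names(genus_means) <- genera
    sp_means <- lapply(design$species, function(sp)
      normalize_shape(genus_means[[design$genus_map[[sp]]]] +
                        matrix(stats::rnorm(2 * k, 0, design$delta), k, 2)))
    names(sp_means) <- design$species
    if (!is.null(design$merge_pair)) {
      a <- design$merge_pair[1]; b <- design$merge_pair[2]
      u <- stats::rnorm(2 * k)
      u <- matrix(u / sqrt(sum(u^2)), k, 2)
      sp_means[[b]] <- normalize_shape(sp_means[[a]] +
                                         design$merge_distance * u)
    }
    ns <- length(design$species)
    size_medians <- exp(seq(log(design$size_median_range[1]),
                            log(design$size_median_range[2]),
                            length.out = ns))
    # assign medians to species in seeded random order
    size_medians <- stats::setNames(sample(size_medians), design$species)
    allo_dir <- matrix(stats::rnorm(2 * k), k, 2)
    allo_dir <- allo_dir / sqrt(sum(allo_dir^2))
    sdlog <- sqrt(log(1 + design$size_cv^2))
    coords <- list(); meta <- list(); true_sizes <- numeric(0)
    for (sp in design$species) {
      n <- design$n_per_species[[sp]]
      sites <- paste0(sp, "_site", seq_len(design$n_sites[[sp]]))
      site_off <- lapply(sites, function(s)
        matrix(stats::rnorm(2 * k, 0, design$sigma_site), k, 2))
      names(site_off) <- sites
      site_of <- sample(rep_len(sites, n))
      cs <- stats::rlnorm(n, log(size_medians[[sp]]), sdlog)
      for (i in seq_len(n)) {
        shp <- sp_means[[sp]] + site_off[[site_of[i]]] +
          matrix(stats::rnorm(2 * k, 0, design$sigma_w), k, 2)
        if (design$beta > 0)
          shp <- shp + design$beta * (log(cs[i]) - log(size_medians[[sp]])) *
            allo_dir
        shp <- normalize_shape(shp) * cs[i]
        th <- stats::runif(1, 0, 2 * pi)
        shp <- rotate_config(shp, th)
        shp <- sweep(shp, 2, stats::runif(2, -10, 10), "+")
        coords[[length(coords) + 1L]] <- shp
        meta[[length(meta) + 1L]] <- data.frame(
          specimen = sprintf("%s_%02d", sp, i), species = sp,
          genus = design$genus_map[[sp]], site = site_of[i],
          stringsAsFactors = FALSE)
        true_sizes <- c(true_sizes, cs[i])
      }
    }
    truth_means <- array(unlist(sp_means), dim = c(k, 2, ns),
                         dimnames = list(NULL, c("x", "y"), design$species))
    dataset <- landmark_dataset(coords, do.call(rbind, meta))
    list(dataset = dataset,
         truth = list(mean_shapes = truth_means,
                      genus_map = design$genus_map,
                      true_sizes = stats::setNames(true_sizes,
                                                   dataset$meta$specimen),
                      size_medians = size_medians,
                      allometry_direction = allo_dir,
                      design = design, seed = seed))
  })
}

#' Simulate repeated landmark digitizations by several observers
#'
#' Emulates the observer-error protocol: a fixed number of specimens per
#' species is re-measured by each of several observers, each replicate
#' being the original configuration plus isotropic digitization noise.
#' The noise standard deviation is `sigma_obs` in shape units, i.e. scaled
#' by each specimen's centroid size in raw coordinates.
#'
#' @param dataset a [landmark_dataset()] (raw coordinates)
#' @param n_specimens_per_species specimens re-measured per species
#'   (default 3)
#' @param n_observers number of observers (default 4)
#' @param sigma_obs digitization noise in shape units
#' @param seed integer seed
#' @return a [landmark_dataset()] of replicates with `observer` and
#'   `replicate` metadata set and `specimen` ids matching the originals
#' @export
simulate_observer_replicates <- function(dataset, n_specimens_per_species = 3,
                                         n_observers = 4, sigma_obs = 0.0026,
                                         seed = 1) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  meta <- dataset$meta
  k <- dataset$k
  with_seed(seed, {
    coords <- list(); rows <- list()
    for (sp in unique(meta$species)) {
      idx <- which(meta$species == sp)
      if (length(idx) < n_specimens_per_species)
        stop("species ", sp, " has fewer than ", n_specimens_per_species,
             " specimens")
      pick <- sample(idx, n_specimens_per_species)
      for (i in pick) {
        cs <- centroid_size(dataset$coords[, , i])
        for (ob in seq_len(n_observers)) {
          coords[[length(coords) + 1L]] <- dataset$coords[, , i] +
            matrix(stats::rnorm(2 * k, 0, sigma_obs * cs), k, 2)
          rows[[length(rows) + 1L]] <- data.frame(
            specimen = meta$specimen[i], species = sp,
            genus = meta$genus[i], site = meta$site[i],
            observer = paste0("obs", ob), replicate = as.character(ob),
            stringsAsFactors = FALSE)
        }
      }
    }
    landmark_dataset(coords, do.call(rbind, rows))
  })
}

#' Simulate a DNA alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies and
#' evolved along each branch with the model's transition probabilities;
#' with a +Gamma model every site carries its own rate drawn from
#' Gamma(alpha, alpha).
#'
#' @param tree a `phylo` tree with branch lengths (substitutions/site)
#' @param model a [substitution_model()]
#' @param length alignment length in bp (default 550)
#' @param seed integer seed
#' @return character matrix (taxa x sites) of A/C/G/T
#' @export
simulate_sequences <- function(tree, model, length = 550, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rates <- if (model$gamma)
      stats::rgamma(length, model$alpha, model$alpha) else rep(1, length)
    po <- ape::reorder.phylo(tree, "cladewise")
    n <- length(po$tip.label)
    nn <- n + po$Nnode
    root <- po$edge[1, 1]
    states <- matrix(NA_integer_, nn, length)
    states[root, ] <- sample.int(4, length, replace = TRUE, prob = model$pi)
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t <- po$edge.length[e]
      child <- integer(length)
      for (st in 1:4) {
        sel <- which(states[p, ] == st)
        if (!length(sel)) next
        # P(t * r) rows for parent state st, vectorized over site rates
        E <- exp(outer(model$eigenvalues, t * rates[sel]))   # 4 x |sel|
        probs <- crossprod(model$V, model$U[st, ] * E)       # 4 x |sel|
        probs[probs < 0] <- 0
        probs <- sweep(probs, 2, colSums(probs), "/")
        u <- stats::runif(length(sel))
        cum <- apply(probs, 2, cumsum)
        child[sel] <- 1L + colSums(cum < rep(u, each = 4))
      }
      states[ch, ] <- child
    }
    aln <- matrix(bases[states[seq_len(n), , drop = FALSE]], n, length)
    rownames(aln) <- po$tip.label
    aln
  })
}
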