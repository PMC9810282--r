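#' Cohort configuration for the synthetic connectome generator
#'
#' Bundles the parameters of the latent-factor cohort model. Regions load on
#' one shared global latent signal plus one latent per module; pairwise
#' Pearson correlation of the resulting time series gives each subject's
#' connectivity matrix, which guarantees a valid correlation structure.
#' The disease effect is mechanistic: anterior regions' loading on the global
#' latent is multiplied by `anterior_attenuation` (weakening anterior-to-
#' posterior coupling, the prefrontal-disconnect phenotype) while the core
#' posterior module's own-module loading is multiplied by `core_boost`
#' (strengthening the core network).
#'
#' @param n_regions even number of regions (default 90: 45 bilateral pairs).
#' @param n_per_group subjects per group (default 17).
#' @param n_modules number of modules (default 6; module 1 is the anterior
#'   prefrontal block, module `n_modules` the posterior/cerebellar core).
#' @param base_coupling own-module latent loading (default 0.45).
#' @param cross_coupling global-latent loading of the most anterior module
#'   (default 0.55); module loadings on the global latent ramp linearly from
#'   here up to `posterior_coupling`, so posterior modules cohere into one
#'   core network after thresholding while the anterior block attaches only
#'   weakly.
#' @param posterior_coupling global-latent loading of the most posterior
#'   (core) module (default 0.95).
#' @param anterior_attenuation factor in \[0, 1\] on the disease group's
#'   anterior global-latent loading (default 0.3; 1 = no effect).
#' @param core_boost factor >= 1 on the disease group's core-module loading
#'   (default 1.6; 1 = no effect).
#' @param n_timepoints time-series length (default 180 acquisition volumes).
#' @param noise_sd i.i.d. Gaussian observation noise (default 1).
#' @param signal_sdlog log-SD of the per-region lognormal signal scale
#'   (default 0.3); heterogeneous scales give weakly-correlated peripheral
#'   regions and a heavy-tailed strength/degree distribution.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_regions = 90L, n_per_group = 17L, n_modules = 6L,
                          base_coupling = 0.45, cross_coupling = 0.55,
                          posterior_coupling = 0.95,
                          anterior_attenuation = 0.3, core_boost = 1.6,
                          n_timepoints = 180L, noise_sd = 1,
                          signal_sdlog = 0.3, seed = 42L) {
  stopifnot(n_regions %% 2 == 0, n_regions >= 4,
            anterior_attenuation >= 0, anterior_attenuation <= 1,
            core_boost >= 1, n_modules >= 1, n_timepoints >= 10)
  structure(list(n_regions = as.integer(n_regions),
                 n_per_group = as.integer(n_per_group),
                 n_modules = as.integer(n_modules),
                 base_coupling = base_coupling,
                 cross_coupling = cross_coupling,
                 posterior_coupling = posterior_coupling,
                 anterior_attenuation = anterior_attenuation,
                 core_boost = core_boost,
                 n_timepoints = as.integer(n_timepoints),
                 noise_sd = noise_sd, signal_sdlog = signal_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a bilaterally mirrored synthetic atlas
#'
#' Creates `n_regions/2` left regions and their mirrored right partners on an
#' anterior-posterior gradient: pair i sits at a y coordinate running from
#' +10 mm (anterior) to -10 mm (posterior), x mirrored about the midline, z
#' jittered. Modules are contiguous anterior-to-posterior blocks of pairs,
#' mirrored across hemispheres (module 1 = anterior, last module = posterior
#' core).
#'
#' @param n_regions even integer >= 4.
#' @param seed RNG seed for the coordinate jitter.
#' @param n_modules number of module blocks (default 6).
#' @return a `region_atlas` with a `module` column.
#' @export
generate_atlas <- function(n_regions = 90L, seed = 1L, n_modules = 6L) {
  if (n_regions %% 2 != 0 || n_regions < 4) {
    stop("n_regions must be an even integer >= 4")
  }
  npair <- n_regions / 2
  with_seed(seed, {
    y <- seq(10, -10, length.out = npair) + stats::rnorm(npair, 0, 0.2)
    x_off <- stats::runif(npair, 1.5, 4.5)
    z <- stats::rnorm(npair, 0, 1.5)
    module <- if (n_modules == 1) rep(1L, npair) else
      as.integer(cut(seq_len(npair), breaks = n_modules, labels = FALSE))
    stem <- sprintf("Region%02d", seq_len(npair))
    region_atlas(label = c(paste0(stem, "_L"), paste0(stem, "_R")),
                 hemisphere = rep(c("L", "R"), each = npair),
                 x = c(-x_off, x_off), y = rep(y, 2), z = rep(z, 2),
                 module = rep(module, 2))
  })
}

# internal: deterministic per-subject seed from (cohort seed, group, index)
subject_seed <- function(seed, group, idx) {
  off <- if (group == "disease") 104729 else 0
  (as.numeric(seed) * 7919 + off + idx * 7907) %% 2147483647
}

# internal: region loading matrix (n_regions x (1 + n_modules)):
# column 1 = global latent, column 1+m = module m latent
region_loadings <- function(atlas, cfg, group) {
  n <- nrow(atlas)
  module <- atlas$module
  nm <- cfg$n_modules
  # global-latent loading ramps anterior -> posterior; own-module loading flat
  gl <- seq(cfg$cross_coupling, cfg$posterior_coupling, length.out = nm)
  bc <- rep(cfg$base_coupling, nm)
  if (group == "disease") {
    gl[1] <- gl[1] * cfg$anterior_attenuation   # anterior disconnect
    bc[nm] <- bc[nm] * cfg$core_boost           # core strengthening: the core
    gl[nm] <- gl[nm] * cfg$core_boost           # module couples harder both
  }                                             # within itself and globally
  # per-region signal scale, fixed by the cohort seed (shared "anatomy")
  s <- with_seed(cfg$seed + 1201L,
                 stats::rlnorm(n, meanlog = 0, sdlog = cfg$signal_sdlog))
  L <- matrix(0, n, 1 + nm)
  L[, 1] <- s * gl[module]
  L[cbind(seq_len(n), 1 + module)] <- s * bc[module]
  L
}

#' Generate one subject's connectivity matrix
#'
#' Simulates `n_timepoints` samples of the latent signals (one global + one
#' per module, i.i.d. standard normal), forms region time series as
#' loadings x latents + Gaussian noise, and returns the region-by-region
#' Pearson correlation matrix with a zeroed diagonal.
#'
#' @param atlas atlas from [generate_atlas()] (must carry modules).
#' @param cfg a `cohort_config`.
#' @param group `"control"` or `"disease"`.
#' @param seed subject RNG seed.
#' @param subject_id identifier string.
#' @return a raw `connectivity_matrix`.
#' @export
generate_subject_matrix <- function(atlas, cfg, group = c("control", "disease"),
                                    seed = 1L, subject_id = "") {
  group <- match.arg(group)
  if (!"module" %in% names(atlas)) stop("atlas must carry a module column")
  if (cfg$n_timepoints < 10) stop("n_timepoints must be >= 10")
  L <- region_loadings(atlas, cfg, group)
  n <- nrow(atlas)
  tp <- cfg$n_timepoints
  x <- with_seed(seed, {
    latents <- matrix(stats::rnorm(tp * ncol(L)), ncol(L), tp)
    L %*% latents + cfg$noise_sd * matrix(stats::rnorm(n * tp), n, tp)
  })
  w <- stats::cor(t(x))
  diag(w) <- 0
  connectivity_matrix(w, labels = atlas$label, subject_id = subject_id,
                      group = group, state = "raw")
}

#' Generate a two-group synthetic cohort
#'
#' `n_per_group` control and disease subjects, each with an independent
#' derived seed, over a shared generated atlas. Fully reproducible from the
#' configuration alone.
#'
#' @param cfg a `cohort_config`.
#' @return list with `control` and `disease` (lists of raw
#'   `connectivity_matrix`), `atlas` and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  atlas <- generate_atlas(cfg$n_regions, seed = cfg$seed, n_modules = cfg$n_modules)
  make <- function(group) {
    lapply(seq_len(cfg$n_per_group), function(i) {
      generate_subject_matrix(atlas, cfg, group = group,
                              seed = subject_seed(cfg$seed, group, i),
                              subject_id = sprintf("%s%02d", substr(group, 1, 1), i))
    })
  }
  list(control = make("control"), disease = make("disease"),
       atlas = atlas, config = cfg)
}

#' Write a cohort to disk
#'
#' One labelled CSV adjacency per subject, the atlas as TSV, and a JSON
#' snapshot of the configuration.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (grp in c("control", "disease")) {
    for (m in cohort[[grp]]) {
      write_matrix(m, file.path(dir, paste0(grp, "_", m$subject_id, ".csv")))
    }
  }
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
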