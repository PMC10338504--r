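#' Run a preconfigured experiment
#'
#' Reproduction drivers for the analyses the package is built around. Each
#' preset runs entirely from its recorded configuration; deterministic presets
#' are bit-reproducible, stochastic ones record their seed.
#'
#' Available presets:
#' * `"fig2-timeout"`: both information settings in the timeout game
#'   `q = (1,0,0;1,1,1)` at default parameters; reports the evolved averages
#'   and the value of information.
#' * `"fig2-conditional-return"`: the same for the timeout game with
#'   conditional return `q = (1,0,0;1,1,0)`.
#' * `"fig4-classification"`: weak-selection classification of all 64
#'   deterministic games.
#' * `"fig5-family"`: the value of information across the recovery
#'   probability for the single-stochastic family `(1,0,0;q,0,0)`.
#' * `"grid-scan"`: a seeded subsample of the full 6-entry grid.
#'
#' @param name preset name.
#' @param overrides named list overriding configuration entries (e.g.
#'   `list(beta = 1)`; allowed names: `b1`, `b2`, `c`, `epsilon`, `N`, `beta`,
#'   `mu`, `grid`, `subsample`, `seed`).
#' @param out_dir if non-`NULL`, results are written there as CSV plus a JSON
#'   sidecar embedding the full configuration, seed and package version.
#' @returns A list with `config` (the resolved configuration) and `result`
#'   (a tibble; preset-dependent columns).
#' @export
run_preset <- function(name, overrides = list(), out_dir = NULL) {
  presets <- c("fig2-timeout", "fig2-conditional-return", "fig4-classification",
               "fig5-family", "grid-scan")
  if (!name %in% presets) {
    stop("unknown preset; available: ", paste(presets, collapse = ", "), call. = FALSE)
  }
  cfg <- list(b1 = 1.8, b2 = 1.3, c = 1, epsilon = 0.01, N = 100, beta = 10,
              mu = 0.01, grid = seq(0.05, 0.95, by = 0.05), subsample = 50, seed = 1)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("invalid overrides: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(overrides)] <- overrides
  params <- game_parameters(b1 = cfg$b1, b2 = cfg$b2, c = cfg$c, epsilon = cfg$epsilon)
  pop <- population_parameters(N = cfg$N, beta = cfg$beta, mu = cfg$mu)

  result <- switch(
    name,
    "fig2-timeout" = ,
    "fig2-conditional-return" = {
      qv <- if (name == "fig2-timeout") transition_vector(1, 0, 0, 1, 1, 1)
            else transition_vector(1, 0, 0, 1, 1, 0)
      evF <- evolve_population("full", qv, params, pop)
      evN <- evolve_population("none", qv, params, pop)
      dplyr::bind_rows(glance(evF), glance(evN)) |>
        dplyr::mutate(V = evF$gamma_hat - evN$gamma_hat)
    },
    "fig4-classification" = classify_deterministic_games(params),
    "fig5-family" = scan_single_stochastic(grid = cfg$grid, params = params,
                                           beta_list = cfg$beta, popparams = pop,
                                           families = which(
                                             enumerate_single_stochastic_families()$family ==
                                               "(1,0,0;q,0,0)")),
    "grid-scan" = scan_full_grid(params = params, beta = cfg$beta,
                                 subsample = cfg$subsample, seed = cfg$seed,
                                 popparams = pop)
  )
  out <- list(config = c(list(preset = name), cfg), result = result)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, gsub("[^a-z0-9-]", "-", name))
    utils::write.csv(result, paste0(base, ".csv"), row.names = FALSE)
    meta <- c(out$config, list(package_version = as.character(utils::packageVersion("stategames"))))
    jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Generate random transition-vector fixtures
#'
#' Reproducible draws spanning the qualitatively different corners of the
#' transition-vector space: deterministic vectors (at least one from each
#' neutrality class), single-stochastic vectors, and fully interior vectors.
#' Intended for property-style testing.
#'
#' @param seed RNG seed.
#' @param n number of vectors of each kind.
#' @returns A tibble with columns `q` (canonical string), `kind`
#'   (`"deterministic"`, `"single_stochastic"`, `"interior"`) and, for
#'   deterministic rows, `class` (their [neutrality_class()]).
#' @export
fixture_generator <- function(seed = 1, n = 5) {
  set.seed(seed)
  det <- enumerate_deterministic_q()
  # draw deterministic vectors until all four neutrality classes are present
  picked <- sample(nrow(det), n)
  classes <- vapply(det$q[picked], function(s) neutrality_class(transition_vector(s)),
                    character(1))
  want <- c("absorbing", "state-independent", "symmetry", "non-neutral")
  tries <- 0L
  while (!all(want %in% classes) && tries < 200L) {
    tries <- tries + 1L
    cand <- sample(nrow(det), 1)
    cl <- neutrality_class(transition_vector(det$q[cand]))
    if (!cl %in% classes) {
      picked <- c(picked, cand)
      classes <- c(classes, cl)
    }
  }
  det_rows <- tibble::tibble(q = det$q[picked], kind = "deterministic", class = classes)
  ss <- replicate(n, {
    pos <- sample(6, 1)
    qv <- sample(c(0, 1), 6, replace = TRUE)
    qv[pos] <- runif(1, 0.05, 0.95)
    format_transition_vector(transition_vector(qv))
  })
  interior <- replicate(n, format_transition_vector(transition_vector(runif(6, 0.02, 0.98))))
  dplyr::bind_rows(
    det_rows,
    tibble::tibble(q = ss, kind = "single_stochastic", class = NA_character_),
    tibble::tibble(q = interior, kind = "interior", class = NA_character_)
  )
}
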