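# Two-deme demographic models, simulated expected folded 2D SFS, composite
# likelihood, ECM-style fitting with restarts, AIC comparison and bootstrap
# confidence intervals.
#
# Deme 1 is the large refugial island (Choros, "C"); deme 2 is the smaller
# island (Pan de Azucar, "A"). Migration parameters follow the backward
# lineage convention: M_AC is the per-generation probability that a lineage
# currently in A traces its ancestry into C, and conversely for M_CA.
# Epoch "1" is the recent period [0, T1); epoch "0" is the older period
# [T1, T0). Divergence is fixed at T0 = 7000 generations for all models
# except model 2, where it is free.

T0_FIXED <- 7000

#' Define one of the six two-deme demographic models
#'
#' * model 1: full isolation — two stable populations, no migration, fixed
#'   divergence (free: `N_C`, `N_A`; k = 2);
#' * model 2: classical isolation-with-migration — free sizes, both
#'   migration rates and divergence time (free: `N_C`, `N_A`, `M_AC`,
#'   `M_CA`, `T0`; k = 5);
#' * model 3: fixed divergence, constant gene flow, constant sizes (free:
#'   `N_C`, `N_A`, `M_AC`, `M_CA`; k = 4);
#' * model 4: constant sizes, migration regime changes at a free time `T1`
#'   (free: `N_C1`, `N_A1`, `M_AC0`, `M_CA0`, `T1`, `M_AC1`, `M_CA1`;
#'   k = 7);
#' * model 5: constant migration, sizes change at `T1` (free: `N_C0`,
#'   `N_A0`, `N_C1`, `N_A1`, `M_AC`, `M_CA`, `T1`; k = 7);
#' * model 6: both migration and sizes change at `T1` (k = 9).
#'
#' @param id integer 1..6.
#' @param T0 fixed divergence time in generations for models 1 and 3-6
#'   (default 7000).
#' @param size_bounds,mig_bounds,time_bounds lower/upper bounds used both
#'   as box constraints and as log-uniform initialization ranges.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(id, T0 = T0_FIXED,
                              size_bounds = c(10, 1e6),
                              mig_bounds = c(1e-8, 0.1),
                              time_bounds = c(1, NA)) {
  id <- as.integer(id)
  if (!id %in% 1:6) stop("model id must be in 1..6")
  if (is.na(time_bounds[2])) time_bounds[2] <- T0 - 1
  par_names <- switch(id,
    c("N_C", "N_A"),
    c("N_C", "N_A", "M_AC", "M_CA", "T0"),
    c("N_C", "N_A", "M_AC", "M_CA"),
    c("N_C1", "N_A1", "M_AC0", "M_CA0", "T1", "M_AC1", "M_CA1"),
    c("N_C0", "N_A0", "N_C1", "N_A1", "M_AC", "M_CA", "T1"),
    c("N_C0", "N_A0", "N_C1", "N_A1", "M_AC0", "M_CA0", "T1", "M_AC1", "M_CA1"))
  btype <- function(nm) {
    if (grepl("^N_", nm)) size_bounds
    else if (grepl("^M_", nm)) mig_bounds
    else if (nm == "T0") c(10, 1e5)
    else time_bounds
  }
  bounds <- t(vapply(par_names, btype, numeric(2)))
  colnames(bounds) <- c("lower", "upper")
  structure(list(id = id, par_names = par_names, k = length(par_names),
                 bounds = bounds, T0 = T0),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model ", x$id, "> k = ", x$k, ": ",
      paste(x$par_names, collapse = ", "),
      if (x$id != 2) paste0(" (T0 fixed at ", x$T0, ")"), "\n", sep = "")
  invisible(x)
}

# Translate (model, params) into a coalescent_config. n1 haploids are
# sampled in deme C (index 1), n2 in deme A (index 2). Backward lineage
# convention: M_AC moves lineages from A into C, i.e. mig[2, 1].
#' @noRd
model_config <- function(model, params, n1, n2, n_loci = 1L, mu = 9.6e-9,
                         locus_length = 95, seed = 1L) {
  p <- as.list(params)
  bad <- vapply(model$par_names, function(nm)
    is.null(p[[nm]]) || p[[nm]] < model$bounds[nm, "lower"] ||
      p[[nm]] > model$bounds[nm, "upper"], logical(1))
  if (any(bad))
    stop("parameter out of bounds or missing: ",
         paste(model$par_names[bad], collapse = ", "))
  migm <- function(m_ac, m_ca) {
    m <- matrix(0, 2, 2)
    m[2, 1] <- m_ac # lineage in A -> C
    m[1, 2] <- m_ca # lineage in C -> A
    m
  }
  id <- model$id
  if (id == 1) {
    coalescent_config(c(n1, n2), N = c(p$N_C, p$N_A), M = matrix(0, 2, 2),
                      T0 = model$T0, mu = mu, locus_length = locus_length,
                      n_loci = n_loci, seed = seed)
  } else if (id == 2) {
    coalescent_config(c(n1, n2), N = c(p$N_C, p$N_A),
                      M = migm(p$M_AC, p$M_CA), T0 = p$T0, mu = mu,
                      locus_length = locus_length, n_loci = n_loci,
                      seed = seed)
  } else if (id == 3) {
    coalescent_config(c(n1, n2), N = c(p$N_C, p$N_A),
                      M = migm(p$M_AC, p$M_CA), T0 = model$T0, mu = mu,
                      locus_length = locus_length, n_loci = n_loci,
                      seed = seed)
  } else if (id == 4) {
    coalescent_config(c(n1, n2), N = c(p$N_C1, p$N_A1),
                      M = migm(p$M_AC1, p$M_CA1),
                      N_ancient = c(p$N_C1, p$N_A1),
                      M_ancient = migm(p$M_AC0, p$M_CA0),
                      T0 = model$T0, T1 = p$T1, mu = mu,
                      locus_length = locus_length, n_loci = n_loci,
                      seed = seed)
  } else if (id == 5) {
    coalescent_config(c(n1, n2), N = c(p$N_C1, p$N_A1),
                      M = migm(p$M_AC, p$M_CA),
                      N_ancient = c(p$N_C0, p$N_A0),
                      M_ancient = migm(p$M_AC, p$M_CA),
                      T0 = model$T0, T1 = p$T1, mu = mu,
                      locus_length = locus_length, n_loci = n_loci,
                      seed = seed)
  } else {
    coalescent_config(c(n1, n2), N = c(p$N_C1, p$N_A1),
                      M = migm(p$M_AC1, p$M_CA1),
                      N_ancient = c(p$N_C0, p$N_A0),
                      M_ancient = migm(p$M_AC0, p$M_CA0),
                      T0 = model$T0, T1 = p$T1, mu = mu,
                      locus_length = locus_length, n_loci = n_loci,
                      seed = seed)
  }
}

#' Expected folded 2D SFS of a demographic model by coalescent simulation
#'
#' Simulates `n_genealogies` genealogies, accumulates each branch's length
#' into the joint cell indexed by its numbers of descendant lineages in
#' each deme, folds on the pooled minor allele, zeroes the monomorphic
#' cell, and normalizes over the polymorphic support. Deterministic given
#' `seed`.
#'
#' @param model a [demographic_model()].
#' @param params named numeric vector (or list) of the model's free
#'   parameters, within bounds.
#' @param n1,n2 haploid sample sizes in demes C and A.
#' @param n_genealogies Monte Carlo size (default 20000).
#' @param seed integer seed.
#' @param tie tie-fold rule (see [folded_2dsfs()]).
#' @return a `folded_2dsfs` of cell probabilities, with the simulated total
#'   branch-length mass in `attr(, "total_length")`.
#' @export
expected_sfs <- function(model, params, n1, n2, n_genealogies = 20000,
                         seed = 1, tie = "half") {
  cfg <- model_config(model, params, n1, n2, seed = seed)
  ea <- engine_args(cfg)
  set.seed(derive_seed(seed, model$id))
  r <- cpp_sfs_branch(ea$samples, ea$etimes, ea$sizes, ea$migs, ea$merges,
                      as.integer(n_genealogies))
  m <- fold_2d(r$spectrum, tie)
  m[1, 1] <- 0 # monomorphic cell carries no branch mass anyway
  tot <- sum(m)
  if (tot <= 0) stop("no polymorphic branch mass simulated")
  out <- new_folded_2dsfs(m / tot, n1, n2, NA_real_)
  attr(out, "total_length") <- r$total_length
  attr(out, "probability") <- TRUE
  out
}

#' Composite log-likelihood of an observed folded SFS
#'
#' `lnCL = sum_c obs_c * ln(exp_c)` over the polymorphic cells (the
#' monomorphic cell is excluded: SNP panels carry no invariant-site
#' counts). Expected cells below the floor `eps` are raised to `eps` and
#' the expectation renormalized, so observed SNPs in cells the simulation
#' left empty stay finite.
#'
#' @param obs a `folded_2dsfs` of observed (real-valued) counts.
#' @param expd a `folded_2dsfs` of expected probabilities from
#'   [expected_sfs()], same dimensions.
#' @param eps floor for expected cells; default `1 / (10 * total simulated
#'   branch-length mass)` when the expectation carries that attribute,
#'   otherwise `1e-12`.
#' @return natural-log composite likelihood (scalar).
#' @export
composite_loglik <- function(obs, expd, eps = NULL) {
  stopifnot(inherits(obs, "folded_2dsfs"), inherits(expd, "folded_2dsfs"))
  if (!all(dim(obs$counts) == dim(expd$counts)))
    stop("observed and expected spectra have different shapes")
  o <- obs$counts
  e <- expd$counts
  o[1, 1] <- 0
  e[1, 1] <- 0
  if (sum(o) <= 0) stop("observed spectrum is all zero")
  if (is.null(eps)) {
    tl <- attr(expd, "total_length")
    eps <- if (!is.null(tl) && tl > 0) 1 / (10 * tl) else 1e-12
  }
  support <- !obs$mask
  support[1, 1] <- FALSE
  floored <- support & e < eps
  if (any(floored & o > 0))
    pp_log("composite_loglik: ", sum(floored & o > 0),
           " observed cell(s) under the expected floor", verbose = FALSE)
  e[floored] <- eps
  e[support] <- e[support] / sum(e[support])
  sum(o[support & o > 0] * log(e[support & o > 0]))
}

#' @noRd
draw_loguniform <- function(bounds) {
  lo <- log(bounds[, "lower"]); hi <- log(bounds[, "upper"])
  stats::setNames(exp(lo + runif(nrow(bounds)) * (hi - lo)), rownames(bounds))
}

# golden-section maximization of f over [lo, hi] on the log scale,
# a fixed number of interior evaluations
#' @noRd
golden_max <- function(f, lo, hi, n_eval = 8) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  best_x <- if (f1 >= f2) x1 else x2
  best_f <- max(f1, f2)
  for (k in seq_len(max(0, n_eval - 2))) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    }
    if (f1 > best_f) { best_f <- f1; best_x <- x1 }
    if (f2 > best_f) { best_f <- f2; best_x <- x2 }
  }
  list(x = exp(best_x), f = best_f)
}

#' Fit a demographic model to an observed folded 2D SFS
#'
#' Composite-likelihood maximization with multiple restarts: each run draws
#' its starting point log-uniformly within the parameter bounds, then
#' performs ECM-style cycles that maximize one parameter at a time by a
#' golden-section line search on the log scale (a bracket of x8 around the
#' current value, clipped to the bounds), with a fresh simulated expected
#' spectrum per evaluation. All evaluations of a fit share one fixed
#' genealogy stream (sample-average approximation), so the optimized
#' surface is deterministic; run endpoints are rescored on a fresh
#' evaluation before the best run is chosen.
#' Cycling stops at `max_cycles` or when the relative lnCL improvement over
#' a cycle falls below `tol`; the best run is kept.
#'
#' @param obs observed `folded_2dsfs` (counts).
#' @param model a [demographic_model()].
#' @param n_runs independent restarts (default 10).
#' @param max_cycles maximum ECM cycles per run (default 40).
#' @param n_genealogies genealogies per likelihood evaluation (default
#'   20000).
#' @param seed integer seed.
#' @param tol relative lnCL improvement below which a run stops (default
#'   2e-5; on a composite likelihood of order 1e4 SNPs this is of the same
#'   order as the Monte Carlo noise of an evaluation, so runs typically use
#'   their full cycle budget rather than stopping on noise).
#' @param line_evals evaluations per golden-section line search (default 8).
#' @param refine_cycles extra ECM cycles run from the best point over all
#'   restarts, at the full Monte Carlo size and with tight brackets
#'   (default 0: no refinement stage).
#' @param polish_evals if positive, a Nelder-Mead polish of this many
#'   iterations is run on the log-parameter scale from the best point over
#'   all restarts, on the same fixed genealogy stream; the polished point
#'   is kept when its freshly rescored lnCL improves on the best run.
#'   Simplex moves follow the composite-likelihood ridges that
#'   one-parameter-at-a-time searches cannot traverse.
#' @param polish_mirrors also polish from ridge-mirrored images of the
#'   best point (T1 rescaled with recent migration compensated); set to
#'   `FALSE` when the caller already stratifies starting values over T1,
#'   as [fit_model_staged()] does.
#' @param init optional named vector of starting values for a subset of the
#'   parameters (e.g. carried over from a simpler nested model fit); named
#'   parameters start every run at these values, the remaining parameters
#'   are drawn log-uniformly as usual.
#' @param verbose log per-run progress.
#' @return an object of class `sfs_fit`: model id, `par` (MLE vector),
#'   `loglik`, `k`, `AIC`, per-run table, convergence flag.
#' @export
fit_model <- function(obs, model, n_runs = 10, max_cycles = 40,
                      n_genealogies = 20000, seed = 1, tol = 2e-5,
                      line_evals = 8, refine_cycles = 0, polish_evals = 0,
                      polish_mirrors = TRUE, init = NULL, verbose = FALSE) {
  stopifnot(inherits(obs, "folded_2dsfs"), inherits(model, "demographic_model"))
  if (n_runs < 1) stop("n_runs must be >= 1")
  n1 <- obs$n1; n2 <- obs$n2
  eval_lnl <- function(par, eval_seed, G = n_genealogies) {
    e <- expected_sfs(model, par, n1, n2, G, seed = eval_seed)
    composite_loglik(obs, e)
  }
  # Sample-average approximation: one fixed genealogy stream is shared by
  # every likelihood evaluation of the fit, so the optimized surface is
  # deterministic and line searches compare like with like; the final
  # points are rescored on a fresh evaluation.
  saa_seed <- derive_seed(seed, 424242L)
  # Bracket span and Monte Carlo size schedules over the cycle index:
  # coarse global moves on cheap evaluations first, tight brackets on
  # low-noise evaluations late.
  sched_span <- function(cyc, span0) max(1.6, span0 * 0.8^(cyc - 1))
  sched_G <- function(cyc, g_frac0) {
    ceiling(n_genealogies *
              min(1, g_frac0 + (1 - g_frac0) * (cyc - 1) /
                    max(1, max_cycles - 1)))
  }
  # One block of ECM cycles from a given point; `from_cyc` positions the
  # block on the span and Monte Carlo schedules.
  ecm_block <- function(par, run_seed, from_cyc, n_cycles, span0, g_frac0,
                        label) {
    lnl <- -Inf
    converged <- FALSE
    cycles <- 0L
    for (cyc0 in seq_len(n_cycles)) {
      cyc <- from_cyc + cyc0 - 1L
      cycles <- cyc0
      cyc_seed <- saa_seed
      lnl_prev <- lnl
      span <- sched_span(cyc, span0)
      G_c <- sched_G(cyc, g_frac0)
      for (nm in model$par_names) {
        lo <- max(model$bounds[nm, "lower"], par[[nm]] / span)
        hi <- min(model$bounds[nm, "upper"], par[[nm]] * span)
        gs <- golden_max(function(v) {
          p2 <- par; p2[[nm]] <- v
          eval_lnl(p2, cyc_seed, G_c)
        }, lo, hi, n_eval = line_evals)
        par[[nm]] <- gs$x
        lnl <- gs$f
      }
      # conditional maximization along the T1 ridge: the folded spectrum
      # constrains the cumulative recent migration T1 * M_*1 much more
      # tightly than T1 itself, so one line search rescales T1 while
      # holding the epoch-1 cumulative migration fixed
      mig1 <- intersect(c("M_AC1", "M_CA1"), model$par_names)
      if ("T1" %in% model$par_names && length(mig1) > 0) {
        ridge_par <- function(s) {
          p2 <- par
          p2[["T1"]] <- par[["T1"]] * s
          for (nm in mig1) p2[[nm]] <- par[[nm]] / s
          p2
        }
        s_ok <- function(s) {
          p2 <- ridge_par(s)
          all(vapply(c("T1", mig1), function(nm)
            p2[[nm] ] >= model$bounds[nm, "lower"] &&
              p2[[nm]] <= model$bounds[nm, "upper"], logical(1)))
        }
        s_lo <- 1 / span; s_hi <- span
        while (!s_ok(s_lo) && s_lo < 1) s_lo <- s_lo * 1.25
        while (!s_ok(s_hi) && s_hi > 1) s_hi <- s_hi / 1.25
        if (s_lo < 1 && s_hi > 1) {
          gs <- golden_max(function(s) eval_lnl(ridge_par(s), cyc_seed, G_c),
                           s_lo, s_hi, n_eval = line_evals)
          if (gs$f >= lnl) {
            par <- ridge_par(gs$x)
            lnl <- gs$f
          }
        }
      }
      if (verbose)
        pp_log("model ", model$id, " ", label, " cycle ", cyc,
               ": lnCL = ", format(lnl, digits = 8))
      if (is.finite(lnl_prev) && abs(lnl - lnl_prev) < tol * abs(lnl_prev)) {
        converged <- TRUE
        break
      }
    }
    list(par = par, cycles = cycles, converged = converged)
  }
  # Successive-halving multistart: every run starts from a log-uniform
  # draw and gets a short screening block on cheap evaluations; the best
  # quarter of the runs continue through the remaining cycles and the
  # overall best point is kept (optionally refined below). With few runs
  # or few cycles this degenerates to plain full-length runs.
  screen_cycles <- if (n_runs >= 4 && max_cycles >= 4)
    max(2L, ceiling(max_cycles / 4)) else max_cycles
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, 1000L + r)
    set.seed(run_seed)
    par <- draw_loguniform(model$bounds)
    if (!is.null(init)) {
      for (nm in intersect(names(init), model$par_names)) {
        par[[nm]] <- min(max(init[[nm]], model$bounds[nm, "lower"]),
                         model$bounds[nm, "upper"])
      }
    }
    converged <- FALSE
    cycles <- 0L
    if (max_cycles > 0) {
      b <- ecm_block(par, run_seed, 1L, screen_cycles, span0 = 8,
                     g_frac0 = 0.25, label = paste0("run ", r, " (screen)"))
      par <- b$par
      converged <- b$converged
      cycles <- b$cycles
    }
    lnl <- eval_lnl(par, saa_seed)
    runs[[r]] <- list(par = par, loglik = lnl, cycles = cycles,
                      converged = converged, run_seed = run_seed)
  }
  if (screen_cycles < max_cycles) {
    keep <- order(vapply(runs, `[[`, numeric(1), "loglik"),
                  decreasing = TRUE)[seq_len(max(1L, ceiling(n_runs / 4)))]
    for (r in keep) {
      b <- ecm_block(runs[[r]]$par, runs[[r]]$run_seed,
                     from_cyc = screen_cycles + 1L,
                     n_cycles = max_cycles - screen_cycles, span0 = 8,
                     g_frac0 = 0.25, label = paste0("run ", r))
      runs[[r]]$par <- b$par
      runs[[r]]$converged <- b$converged
      runs[[r]]$cycles <- runs[[r]]$cycles + b$cycles
    }
  }
  # score final points on a common fresh evaluation for comparability
  for (r in seq_len(n_runs)) {
    runs[[r]]$loglik <- eval_lnl(runs[[r]]$par, derive_seed(seed, 999L))
  }
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  if (polish_evals > 0) {
    clamp <- function(lp) {
      p <- pmin(pmax(exp(lp), model$bounds[, "lower"]),
                model$bounds[, "upper"])
      names(p) <- model$par_names
      p
    }
    negf <- function(lp) -eval_lnl(clamp(lp), saa_seed)
    # polish from the best run and, for regime-change models, from its
    # ridge-mirrored images (T1 rescaled with the recent migration rates
    # compensated): the T1 x M_*1 ridge carries near-degenerate modes and
    # a single local polish cannot cross between them
    starts <- list(unlist(runs[[which.max(lls)]]$par))
    mig1 <- intersect(c("M_AC1", "M_CA1"), model$par_names)
    if (polish_mirrors && "T1" %in% model$par_names && length(mig1) > 0) {
      for (s in c(1 / 5, 5)) {
        p2 <- starts[[1]]
        p2[["T1"]] <- p2[["T1"]] * s
        for (nm in mig1) p2[[nm]] <- p2[[nm]] / s
        p2 <- pmin(pmax(p2, model$bounds[, "lower"]),
                   model$bounds[, "upper"])
        starts <- c(starts, list(p2))
      }
    }
    for (st in starts) {
      o <- stats::optim(log(st), negf, method = "Nelder-Mead",
                        control = list(maxit = polish_evals, reltol = 1e-9))
      cand <- clamp(o$par)
      cand_lnl <- eval_lnl(as.list(cand), derive_seed(seed, 999L))
      if (cand_lnl >= best$loglik) {
        best <- list(par = as.list(cand), loglik = cand_lnl,
                     cycles = best$cycles, converged = best$converged)
      }
    }
  }
  if (refine_cycles > 0 && max_cycles > 0) {
    rb_seed <- derive_seed(seed, 5000L)
    b <- ecm_block(best$par, rb_seed, 1L, refine_cycles, span0 = 3,
                   g_frac0 = 1, label = "refine")
    lnl <- eval_lnl(b$par, derive_seed(rb_seed, 999L))
    if (lnl >= best$loglik) {
      best <- list(par = b$par, loglik = lnl,
                   cycles = best$cycles + b$cycles,
                   converged = b$converged)
    }
  }
  if (!any(vapply(runs, `[[`, logical(1), "converged")) && max_cycles > 0)
    pp_log("fit_model: no run reached the lnCL tolerance; best attempt returned",
           verbose = verbose)
  structure(list(model_id = model$id, par = unlist(best$par),
                 loglik = best$loglik, k = model$k,
                 AIC = 2 * model$k - 2 * best$loglik,
                 converged = best$converged,
                 runs = data.frame(run = seq_len(n_runs), loglik = lls,
                                   cycles = vapply(runs, `[[`, integer(1), "cycles"),
                                   converged = vapply(runs, `[[`, logical(1), "converged")),
                 n1 = n1, n2 = n2, n_snps = sum(obs$counts),
                 n_genealogies = n_genealogies),
            class = "sfs_fit")
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat("<sfs_fit> model ", x$model_id, ": lnCL = ", format(x$loglik, digits = 8),
      ", k = ", x$k, ", AIC = ", format(x$AIC, digits = 8), "\n", sep = "")
  print(signif(x$par, 4))
  invisible(x)
}

#' Rank model fits by AIC
#'
#' @param fits list of `sfs_fit` objects on the same observed spectrum.
#' @return data.frame sorted by ascending AIC with `delta_AIC` and Akaike
#'   weights.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 1) stop("no fits")
  sig <- vapply(fits, function(f) paste(f$n1, f$n2, format(f$n_snps, digits = 12)),
                character(1))
  if (length(unique(sig)) != 1)
    stop("fits were not computed on the same observed spectrum")
  tab <- data.frame(
    model = vapply(fits, `[[`, integer(1), "model_id"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  w <- exp(-tab$delta_AIC / 2)
  tab$akaike_weight <- w / sum(w)
  rownames(tab) <- NULL
  tab
}

#' Bootstrap confidence intervals for a fitted model
#'
#' Refits the model on each bootstrap spectrum (a reduced run budget is
#' standard) and reports percentile 2.5/50/97.5 summaries per parameter.
#'
#' @param boot_sfs list of `folded_2dsfs` replicates from
#'   [bootstrap_sfs()] (at least 2).
#' @param model a [demographic_model()].
#' @param n_runs,max_cycles,n_genealogies fit budget per replicate.
#' @param seed integer seed.
#' @param ... further arguments to [fit_model()].
#' @return data.frame with `parameter`, `median`, `ci_lower`, `ci_upper`,
#'   plus the per-replicate estimates in `attr(, "replicates")`.
#' @export
bootstrap_cis <- function(boot_sfs, model, n_runs = 2, max_cycles = 10,
                          n_genealogies = 5000, seed = 1, ...) {
  if (length(boot_sfs) < 2) stop("need at least two bootstrap replicates")
  est <- t(vapply(seq_along(boot_sfs), function(b) {
    # one common fit seed across replicates: identical replicates refit
    # identically, and optimizer noise is shared (common random numbers)
    # so CI width reflects data variation only
    fit <- fit_model(boot_sfs[[b]], model, n_runs = n_runs,
                     max_cycles = max_cycles,
                     n_genealogies = n_genealogies,
                     seed = derive_seed(seed, 1L), ...)
    fit$par
  }, stats::setNames(numeric(model$k), model$par_names)))
  q <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  out <- data.frame(parameter = colnames(est), median = q[2, ],
                    ci_lower = q[1, ], ci_upper = q[3, ],
                    row.names = NULL)
  attr(out, "replicates") <- est
  out
}

#' Published full-scale fitting budget
#'
#' The optimization scheme of the original reconstructions: 50 parallel
#' runs per model, a maximum of 80 ECM cycles per run, 100,000 simulated
#' spectra per likelihood evaluation, and 50 nonparametric bootstrap
#' replicates each refit with the same run budget. Pass these values to
#' [fit_model()] / [bootstrap_cis()] to restore the full budget (cluster
#' scale: hours to days of CPU); desk-scale defaults are documented in the
#' methods vignette.
#'
#' @return named list with `n_runs`, `max_cycles`, `n_genealogies`,
#'   `n_bootstrap`.
#' @export
paper_budget <- function() {
  list(n_runs = 50L, max_cycles = 80L, n_genealogies = 100000L,
       n_bootstrap = 50L)
}

# warm-start mapping from a constant-migration fit to a richer model
#' @noRd
warm_from_nested <- function(model, nested_par, t1) {
  np <- as.list(nested_par)
  out <- switch(as.character(model$id),
    "4" = c(N_C1 = np$N_C, N_A1 = np$N_A, M_AC0 = np$M_AC, M_CA0 = np$M_CA,
            T1 = t1, M_AC1 = np$M_AC, M_CA1 = np$M_CA),
    "5" = c(N_C0 = np$N_C, N_A0 = np$N_A, N_C1 = np$N_C, N_A1 = np$N_A,
            M_AC = np$M_AC, M_CA = np$M_CA, T1 = t1),
    "6" = c(N_C0 = np$N_C, N_A0 = np$N_A, N_C1 = np$N_C, N_A1 = np$N_A,
            M_AC0 = np$M_AC, M_CA0 = np$M_CA, T1 = t1,
            M_AC1 = np$M_AC, M_CA1 = np$M_CA),
    stop("staged fitting applies to the regime/size-change models (4-6)"))
  pmin(pmax(out, model$bounds[names(out), "lower"]),
       model$bounds[names(out), "upper"])
}

#' Staged fit of a regime- or size-change model by T1 profiling
#'
#' The regime-change time T1 is the hardest parameter of models 4-6: the
#' folded spectrum constrains it only jointly with the epoch-1 rates, so
#' free simplex or coordinate searches stall on the ridge and rarely move
#' T1 off its starting value. The staged procedure treats T1 as a profile
#' parameter instead: (1) the constant-migration model 3 is fitted to pin
#' deme sizes and average gene flow; (2) sweeping an ascending log-spaced
#' T1 grid, the remaining parameters are maximized by a simplex search at
#' each FIXED T1 - a well-conditioned subproblem - with each grid point
#' warm-started from its predecessor (continuation) and all evaluations on
#' one fixed genealogy stream, so the profile values are directly
#' comparable; (3) a final full-dimensional polish with T1 free starts
#' from the profile maximum; (4) the result is rescored on a fresh
#' high-precision evaluation.
#'
#' @param obs observed `folded_2dsfs` (counts).
#' @param model a [demographic_model()] with id 4, 5 or 6.
#' @param seed integer seed.
#' @param t1_grid ascending profile grid for T1 (default 6 log-spaced
#'   points spanning 40-6100 generations).
#' @param n_genealogies Monte Carlo size of the deep polish evaluations
#'   (the profile triage runs at 40% of it).
#' @param profile_evals simplex iterations per profile point (the first,
#'   coldest point gets 2x).
#' @param polish_evals simplex iterations of each deep free-T1 polish.
#' @param nested_fit optionally a precomputed `sfs_fit` of model 3 on the
#'   same spectrum (skips stage 1).
#' @param nested_args fitting budget for stage 1.
#' @return an `sfs_fit` for `model`, with the profile table in
#'   `$profile` and the nested fit in `$nested_fit`.
#' @export
fit_model_staged <- function(obs, model, seed = 1,
                             t1_grid = round(exp(seq(log(40), log(6100),
                                                     length.out = 6))),
                             n_genealogies = 3000, profile_evals = 150,
                             polish_evals = 800, nested_fit = NULL,
                             nested_args = list(n_runs = 4, max_cycles = 4,
                                                line_evals = 5,
                                                polish_evals = 150)) {
  stopifnot(inherits(obs, "folded_2dsfs"), inherits(model, "demographic_model"))
  if (!"T1" %in% model$par_names)
    stop("staged fitting applies to the regime/size-change models (4-6)")
  if (is.null(nested_fit)) {
    m3 <- demographic_model(3,
                            size_bounds = range(model$bounds[grep("^N_", model$par_names), ]),
                            mig_bounds = range(model$bounds[grep("^M_", model$par_names), ]))
    nested_fit <- do.call(fit_model, c(list(obs, m3, seed = seed,
                                            n_genealogies = n_genealogies),
                                       nested_args))
  }
  t1_grid <- sort(pmin(pmax(t1_grid, model$bounds["T1", "lower"]),
                       model$bounds["T1", "upper"]))
  saa <- derive_seed(seed, 424242L)
  G_prof <- max(500L, ceiling(0.4 * n_genealogies))
  lnl_saa <- function(p) {
    composite_loglik(obs, expected_sfs(model, p, obs$n1, obs$n2,
                                       G_prof, seed = saa))
  }
  free <- setdiff(model$par_names, "T1")
  lb <- model$bounds[free, "lower"]
  ub <- model$bounds[free, "upper"]
  prof_point <- function(start, t1, evals) {
    negf <- function(lp) {
      p <- stats::setNames(pmin(pmax(exp(lp), lb), ub), free)
      -lnl_saa(c(p, T1 = t1))
    }
    o <- stats::optim(log(start), negf, method = "Nelder-Mead",
                      control = list(maxit = evals, reltol = 1e-9))
    list(par = stats::setNames(pmin(pmax(exp(o$par), lb), ub), free),
         loglik = -o$value)
  }
  # Profile sweep with continuation: maximize the non-T1 parameters at
  # each fixed T1, warm-starting from the neighbouring grid point's
  # optimum. Two passes, ascending then descending, keeping the better
  # value per point: a single directed sweep lets later points accumulate
  # more total optimization than earlier ones and biases the profile
  # argmax toward the sweep's end.
  cur <- warm_from_nested(model, nested_fit$par, t1_grid[1])[free]
  profile <- vector("list", length(t1_grid))
  for (i in seq_along(t1_grid)) {
    r <- prof_point(cur, t1_grid[i],
                    if (i == 1) 2 * profile_evals else profile_evals)
    cur <- r$par
    profile[[i]] <- list(T1 = t1_grid[i], par = r$par, loglik = r$loglik)
  }
  for (i in rev(seq_len(length(t1_grid) - 1))) {
    r <- prof_point(profile[[i + 1]]$par, t1_grid[i], profile_evals)
    if (r$loglik > profile[[i]]$loglik) {
      profile[[i]]$par <- r$par
      profile[[i]]$loglik <- r$loglik
    }
  }
  prof_lnl <- vapply(profile, `[[`, numeric(1), "loglik")
  # deep free-T1 simplex polish from the two leading profile points; the
  # triage subproblems rank the T1 regions, the deep phase converges the
  # finalists at full Monte Carlo size (free polish also recovers the
  # likelihood a fixed-T1 conditional optimum leaves on the table, which
  # matters for AIC comparisons against simpler models)
  top <- order(prof_lnl, decreasing = TRUE)[seq_len(min(2, length(profile)))]
  starts <- lapply(top, function(i) c(profile[[i]]$par,
                                      T1 = profile[[i]]$T1))
  # also polish from the nested model's own optimum mapped into this
  # model (equal epochs, mid-grid T1): the richer model nests the
  # constant-migration one, so its fitted likelihood should never fall
  # below the nested fit's, and this candidate guarantees that
  starts <- c(starts, list(warm_from_nested(model, nested_fit$par,
                                            exp(mean(log(range(t1_grid)))))))
  finals <- lapply(starts, function(st) {
    fit_model(obs, model, n_runs = 1, max_cycles = 0,
              n_genealogies = n_genealogies, seed = seed,
              polish_evals = polish_evals, polish_mirrors = FALSE,
              init = st)
  })
  score <- vapply(finals, function(f) {
    e <- expected_sfs(model, f$par, obs$n1, obs$n2,
                      n_genealogies = max(15000, n_genealogies),
                      seed = derive_seed(seed, 31L))
    composite_loglik(obs, e)
  }, numeric(1))
  fit <- finals[[which.max(score)]]
  fit$loglik <- max(score)
  fit$AIC <- 2 * model$k - 2 * fit$loglik
  fit$profile <- data.frame(T1 = t1_grid, loglik = prof_lnl)
  fit$nested_fit <- nested_fit
  fit
}
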