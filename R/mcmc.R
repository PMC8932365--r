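# Metropolis-within-Gibbs samplers for the hierarchical trend model
# (compiled front-end plus a pure-R reference implementation).
#
# Location parameters (country/region/global coefficients, quintile offsets)
# have Normal full conditionals and are drawn exactly (Gibbs). Scale
# parameters (hierarchical sds, the noise sd, the quintile shrinkage sd) are
# non-conjugate under the Gamma-on-sd and Uniform priors and are updated by
# random-walk Metropolis on the log scale with the Jacobian correction.
# Step sizes adapt toward 44% acceptance during burn-in only (Robbins-Monro),
# and are frozen afterward so retained draws satisfy detailed balance.

#' Sampler configuration
#'
#' Defaults follow the reference MCMC settings: 10 000 iterations, 3 chains,
#' thinning 10 and a 2000-iteration burn-in, which retain
#' `(iterations - burn_in) / thin = 800` draws per chain (2400 total).
#'
#' @param iterations iterations per chain (including burn-in).
#' @param chains number of chains (at least 2 for Gelman-Rubin diagnostics).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param burn_in iterations discarded per chain; must be `< iterations`.
#' @param seed integer seed; each chain derives its own stream from it.
#' @param adapt adapt Metropolis step sizes during burn-in.
#' @param step_init initial log-scale random-walk step size.
#' @return an object of class `anc_sampler_config`.
#' @export
sampler_config <- function(iterations = 10000L, chains = 3L, thin = 10L,
                           burn_in = 2000L, seed = 1L, adapt = TRUE,
                           step_init = 0.3) {
  iterations <- as.integer(iterations); chains <- as.integer(chains)
  thin <- as.integer(thin); burn_in <- as.integer(burn_in)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (chains < 1L) stop("chains must be >= 1")
  if (burn_in < 0L) stop("burn_in must be non-negative")
  structure(list(iterations = iterations, chains = chains, thin = thin,
                 burn_in = burn_in, seed = as.integer(seed),
                 adapt = isTRUE(adapt), step_init = step_init,
                 n_retained = (iterations - burn_in) %/% thin),
            class = "anc_sampler_config")
}

# parameter layout shared by packing, naming and reconstruction
make_layout <- function(md) {
  coefs <- colnames(md$X)
  list(p = md$p, coefs = coefs,
       countries = md$countries, regions = md$regions,
       region_of_country = md$region_of_country,
       quint = !is.null(md$quintile),
       use_covariates = md$use_covariates,
       scale = md$scale)
}

mat_names <- function(prefix, rows, cols) {
  paste0(prefix, "[", rep(rows, times = length(cols)), ",",
         rep(cols, each = length(rows)), "]")
}

layout_names <- function(lay) {
  nm <- c(paste0("beta[", lay$coefs, "]"),
          mat_names("beta_region", lay$regions, lay$coefs),
          mat_names("beta_country", lay$countries, lay$coefs),
          mat_names("sigma_region", lay$regions, lay$coefs),
          paste0("sigma_global[", lay$coefs, "]"),
          "tau")
  if (lay$quint) {
    nm <- c(nm, mat_names("q_int", lay$countries, paste0("Q", 1:5)),
            mat_names("q_slope", lay$countries, paste0("Q", 1:5)),
            "sigma_q_int", "sigma_q_slope")
  }
  nm
}

pack_state <- function(state, lay) {
  v <- c(state$global_beta, as.vector(state$region_beta),
         as.vector(state$country_beta), as.vector(state$region_sd),
         state$global_sd, state$obs_sd)
  if (lay$quint) {
    v <- c(v, as.vector(state$q_int), as.vector(state$q_slope),
           state$q_sd_int, state$q_sd_slope)
  }
  v
}

unpack_state <- function(v, lay) {
  p <- lay$p; J <- length(lay$regions); K <- length(lay$countries)
  i <- 0L
  take <- function(n) { out <- v[(i + 1L):(i + n)]; i <<- i + n; out }
  state <- list(
    global_beta = stats::setNames(take(p), lay$coefs),
    region_beta = matrix(take(J * p), J, p, dimnames = list(lay$regions, lay$coefs)),
    country_beta = matrix(take(K * p), K, p, dimnames = list(lay$countries, lay$coefs)),
    region_sd = matrix(take(J * p), J, p, dimnames = list(lay$regions, lay$coefs)),
    global_sd = stats::setNames(take(p), lay$coefs),
    obs_sd = take(1L)
  )
  if (lay$quint) {
    state$q_int <- matrix(take(K * 5L), K, 5L,
                          dimnames = list(lay$countries, paste0("Q", 1:5)))
    state$q_slope <- matrix(take(K * 5L), K, 5L,
                            dimnames = list(lay$countries, paste0("Q", 1:5)))
    state$q_sd_int <- take(1L)
    state$q_sd_slope <- take(1L)
  }
  class(state) <- "anc_state"
  state
}

# Marginal log-likelihood of one country's data with its coefficient vector
# integrated out: y_k - X_k beta_region ~ N(0, X_k S X_k' + tau^2 I) with
# S = diag(s2). Evaluated through the Woodbury identity, so only a p x p
# factorization is needed. `rr` = sum of squared residuals, `Xr` = X'r.
marg_country_ll <- function(n, XtX, rr, Xr, d, tau2, dix) {
  p <- length(d)
  G <- (d * XtX) * rep(d, each = p)
  G[dix] <- G[dix] + tau2
  U <- chol.default(G)
  v <- backsolve(U, d * Xr, transpose = TRUE)
  ldet <- (n - p) * log(tau2) + 2 * sum(log(U[dix]))
  quad <- (rr - sum(v * v)) / tau2
  -0.5 * (n * log(2 * pi) + ldet + quad)
}

# Marginal log-likelihood of region-level country coefficients (one
# coefficient column) with the region means integrated out: per region j,
# x_j ~ N(beta_global * 1, sd_within^2 I + sd_between^2 11').
marg_region_ll <- function(nj, ssw, xbar, beta_g, s2_within, s2_between) {
  v <- s2_within + nj * s2_between
  sum(-0.5 * (nj * log(2 * pi) + (nj - 1) * log(s2_within) + log(v) +
                ssw / s2_within + nj * (xbar - beta_g)^2 / v))
}

# one chain via the compiled sampler (src/sampler.cpp); same model and
# priors as the pure-R reference below, but with the hierarchical sds
# updated against the fully collapsed marginal likelihood (both coefficient
# levels integrated out) and the location parameters redrawn in one exact
# blocked pass down the hierarchy
run_chain_compiled <- function(md, priors, cfg, fixed, init, chain_seed) {
  set.seed(as.integer(chain_seed %% .Machine$integer.max))
  state <- if (is.null(init)) init_state(md) else init
  fix_rs <- !is.null(fixed$region_sd)
  fix_gs <- !is.null(fixed$global_sd)
  fix_tau <- !is.null(fixed$obs_sd)
  if (fix_rs) state$region_sd[, ] <- fixed$region_sd
  if (fix_gs) state$global_sd[] <- fixed$global_sd
  if (fix_tau) state$obs_sd <- fixed$obs_sd
  if (!is.finite(log_posterior(state, md, priors))) {
    stop("initial state outside prior support")
  }
  res <- .sampler_chain_cpp(
    y = md$y, X = md$X,
    country = as.integer(md$country),
    region_of = as.integer(md$region_of_country),
    quintile = if (is.null(md$quintile)) integer(md$n)
               else as.integer(md$quintile),
    init = state,
    prior = list(beta_var = priors$beta_var, sd_shape = priors$sd_shape,
                 sd_rate = priors$sd_rate, tau_upper = priors$tau_upper,
                 halfcauchy_scale = priors$halfcauchy_scale,
                 sd_type = if (priors$sd_prior == "gamma") 0L else 1L),
    cfg = list(iterations = cfg$iterations, burn_in = cfg$burn_in,
               thin = cfg$thin, adapt = cfg$adapt,
               step_init = cfg$step_init),
    fixed = list(fix_rs = fix_rs, fix_gs = fix_gs, fix_tau = fix_tau))
  active <- c(region_sd = !fix_rs, global_sd = !fix_gs, tau = !fix_tau,
              q_sd = !is.null(md$quintile))
  if (cfg$burn_in > 0) {
    for (b in names(active)[active]) {
      if (res$burn_accept[[b]] == 0) {
        warning("zero Metropolis acceptance during burn-in for block ", b)
      }
    }
  }
  list(draws = res$draws, acceptance = res$acceptance[names(active)[active]])
}

# one chain of the Metropolis-within-Gibbs sampler (pure-R reference
# implementation, used to cross-check the compiled sampler)
run_chain <- function(md, priors, cfg, fixed, init, chain_seed) {
  set.seed(as.integer(chain_seed %% .Machine$integer.max))
  p <- md$p; K <- length(md$countries); J <- length(md$regions)
  quint <- !is.null(md$quintile)
  lay <- make_layout(md)
  state <- if (is.null(init)) init_state(md) else init
  fix_rs <- !is.null(fixed$region_sd)
  fix_gs <- !is.null(fixed$global_sd)
  fix_tau <- !is.null(fixed$obs_sd)
  if (fix_rs) state$region_sd[, ] <- fixed$region_sd
  if (fix_gs) state$global_sd[] <- fixed$global_sd
  if (fix_tau) state$obs_sd <- fixed$obs_sd
  if (!is.finite(log_posterior(state, md, priors))) {
    stop("initial state outside prior support")
  }

  rows_k <- split(seq_len(md$n), md$country)
  Xk <- lapply(rows_k, function(r) md$X[r, , drop = FALSE])
  yk <- lapply(rows_k, function(r) md$y[r])
  XtXk <- lapply(Xk, crossprod)
  Xyk <- lapply(seq_len(K), function(k) crossprod(Xk[[k]], yk[[k]])[, 1])
  nk <- lengths(rows_k)
  dix <- seq(1L, p * p, by = p + 1L)   # diagonal indices of a p x p matrix
  region_members <- split(seq_len(K), md$region_of_country)
  if (quint) {
    kq_rows <- split(seq_len(md$n), list(md$country, md$quintile), drop = FALSE)
    kq_idx <- function(k, q) kq_rows[[paste0(k, ".", q)]]
  }

  # adaptive log step sizes
  ls_rs <- matrix(log(cfg$step_init), J, p)
  ls_gs <- rep(log(cfg$step_init), p)
  ls_tau <- log(cfg$step_init)
  ls_q <- log(cfg$step_init)
  acc <- c(region_sd = 0, global_sd = 0, tau = 0, q_sd = 0)
  att <- c(region_sd = 0, global_sd = 0, tau = 0, q_sd = 0)
  burn_acc <- att

  prior_fn <- function(s) log_sd_prior(s, priors)
  n_keep <- cfg$n_retained
  out <- matrix(NA_real_, n_keep, length(layout_names(lay)))
  keep_i <- 0L

  for (it in seq_len(cfg$iterations)) {
    in_burn <- it <= cfg$burn_in
    gam <- if (cfg$adapt && in_burn) min(0.25, 2 / sqrt(it)) else 0
    tau2 <- state$obs_sd^2

    ## outcome net of quintile offsets, per country
    yadjk <- yk
    if (quint) {
      for (k in seq_len(K)) {
        r <- rows_k[[k]]
        idx <- cbind(k, md$quintile[r])
        yadjk[[k]] <- yk[[k]] - state$q_int[idx] -
          state$q_slope[idx] * md$X[r, "year"]
      }
    }

    ## --- between-country sds: component-wise log-scale random walk on
    ##     the partially collapsed posterior (country coefficients
    ##     integrated out analytically), which avoids the funnel degeneracy
    ##     of conditional updates under the near-improper Gamma sd prior
    if (!fix_rs) {
      for (j in seq_len(J)) {
        ks <- region_members[[j]]
        nks <- length(ks)
        rr_j <- numeric(nks)
        Xr_j <- vector("list", nks)
        for (i in seq_len(nks)) {
          k <- ks[i]
          r <- yadjk[[k]] - Xk[[k]] %*% state$region_beta[j, ]
          rr_j[i] <- sum(r * r)
          Xr_j[[i]] <- crossprod(Xk[[k]], r)[, 1]
        }
        d <- state$region_sd[j, ]
        cur_ml <- 0
        for (i in seq_len(nks)) {
          cur_ml <- cur_ml + marg_country_ll(nk[ks[i]], XtXk[[ks[i]]],
                                             rr_j[i], Xr_j[[i]], d, tau2, dix)
        }
        for (cc in seq_len(p)) {
          cur <- d[cc]
          prop <- cur * exp(stats::rnorm(1, 0, exp(ls_rs[j, cc])))
          dp <- d
          dp[cc] <- prop
          prop_ml <- 0
          for (i in seq_len(nks)) {
            prop_ml <- prop_ml + marg_country_ll(nk[ks[i]], XtXk[[ks[i]]],
                                                 rr_j[i], Xr_j[[i]], dp,
                                                 tau2, dix)
          }
          la <- prop_ml + prior_fn(prop) + log(prop) -
            cur_ml - prior_fn(cur) - log(cur)
          ok <- is.finite(la) && log(stats::runif(1)) < la
          if (ok) {
            d <- dp
            state$region_sd[j, cc] <- prop
            cur_ml <- prop_ml
          }
          if (!in_burn) {
            att["region_sd"] <- att["region_sd"] + 1
            acc["region_sd"] <- acc["region_sd"] + ok
          } else burn_acc["region_sd"] <- burn_acc["region_sd"] + ok
          ls_rs[j, cc] <- ls_rs[j, cc] + gam * ((ok) - 0.44)
        }
      }
    }

    ## --- region means: exact Gibbs with country coefficients integrated
    ##     out (y_k | beta_j ~ N(X_k beta_j, X_k S X_k' + tau^2 I)), which
    ##     decouples the hierarchy levels
    for (j in seq_len(J)) {
      ks <- region_members[[j]]
      d <- state$region_sd[j, ]
      P <- diag(1 / state$global_sd^2, p)
      b <- state$global_beta / state$global_sd^2
      for (k in ks) {
        XtX <- XtXk[[k]]
        G <- (d * XtX) * rep(d, each = p)
        G[dix] <- G[dix] + tau2
        Ginv <- chol2inv(chol.default(G))
        DX <- d * XtX
        Xy <- if (quint) crossprod(Xk[[k]], yadjk[[k]])[, 1] else Xyk[[k]]
        GDX <- Ginv %*% DX
        P <- P + (XtX - crossprod(DX, GDX)) / tau2
        b <- b + (Xy - crossprod(GDX, d * Xy)[, 1]) / tau2
      }
      U <- chol.default((P + t(P)) / 2)
      mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
      state$region_beta[j, ] <- mu + backsolve(U, stats::rnorm(p))
    }

    ## --- country coefficient vectors (exact Gibbs)
    for (k in seq_len(K)) {
      j <- md$region_of_country[k]
      pp <- 1 / state$region_sd[j, ]^2
      P <- XtXk[[k]] / tau2
      P[dix] <- P[dix] + pp
      Xy <- if (quint) crossprod(Xk[[k]], yadjk[[k]])[, 1] else Xyk[[k]]
      b <- Xy / tau2 + pp * state$region_beta[j, ]
      U <- chol.default(P)
      mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
      state$country_beta[k, ] <- mu + backsolve(U, stats::rnorm(p))
    }

    ## --- between-region sds, partially collapsed over the region means
    ##     (region means are redrawn below before any further use)
    if (!fix_gs) {
      nj <- lengths(region_members)
      for (cc in seq_len(p)) {
        xs <- lapply(region_members, function(ks) state$country_beta[ks, cc])
        xbar <- vapply(xs, mean, numeric(1))
        ssw <- vapply(xs, function(x) sum((x - mean(x))^2), numeric(1))
        s2w <- state$region_sd[, cc]^2
        cur <- state$global_sd[cc]
        prop <- cur * exp(stats::rnorm(1, 0, exp(ls_gs[cc])))
        la <- marg_region_ll(nj, ssw, xbar, state$global_beta[cc], s2w,
                             prop^2) + prior_fn(prop) + log(prop) -
          marg_region_ll(nj, ssw, xbar, state$global_beta[cc], s2w, cur^2) -
          prior_fn(cur) - log(cur)
        ok <- is.finite(la) && log(stats::runif(1)) < la
        if (ok) state$global_sd[cc] <- prop
        if (!in_burn) {
          att["global_sd"] <- att["global_sd"] + 1
          acc["global_sd"] <- acc["global_sd"] + ok
        } else burn_acc["global_sd"] <- burn_acc["global_sd"] + ok
        ls_gs[cc] <- ls_gs[cc] + gam * ((ok) - 0.44)
      }
    }


    ## --- quintile offsets (exact Gibbs + sum-to-zero sweep)
    if (quint) {
      eta0 <- rowSums(md$X * state$country_beta[md$country, , drop = FALSE])
      pa <- 1 / state$q_sd_int^2
      pb <- 1 / state$q_sd_slope^2
      for (k in seq_len(K)) {
        for (q in 1:5) {
          r <- kq_idx(k, q)
          if (!length(r)) next
          yr <- md$X[r, "year"]
          e <- md$y[r] - eta0[r]
          # intercept offset
          prec <- length(r) / tau2 + pa
          m <- sum(e - state$q_slope[k, q] * yr) / tau2 / prec
          state$q_int[k, q] <- stats::rnorm(1, m, sqrt(1 / prec))
          # slope offset
          prec <- sum(yr^2) / tau2 + pb
          m <- sum((e - state$q_int[k, q]) * yr) / tau2 / prec
          state$q_slope[k, q] <- stats::rnorm(1, m, sqrt(1 / prec))
        }
      }
      # identification sweep: move per-country offset means into the
      # country intercept / year slope
      am <- rowMeans(state$q_int)
      bm <- rowMeans(state$q_slope)
      state$q_int <- state$q_int - am
      state$q_slope <- state$q_slope - bm
      state$country_beta[, "intercept"] <- state$country_beta[, "intercept"] + am
      state$country_beta[, "year"] <- state$country_beta[, "year"] + bm
    }

    ## --- region means (exact Gibbs, coefficient-wise)
    for (j in seq_len(J)) {
      ks <- region_members[[j]]
      nj <- length(ks)
      prec <- nj / state$region_sd[j, ]^2 + 1 / state$global_sd^2
      m <- (colSums(state$country_beta[ks, , drop = FALSE]) /
              state$region_sd[j, ]^2 + state$global_beta / state$global_sd^2) / prec
      state$region_beta[j, ] <- stats::rnorm(p, m, sqrt(1 / prec))
    }

    ## --- global mean (exact Gibbs)
    prec <- J / state$global_sd^2 + 1 / priors$beta_var
    m <- (colSums(state$region_beta) / state$global_sd^2) / prec
    state$global_beta <- stats::rnorm(p, m, sqrt(1 / prec))

    ## --- quintile shrinkage sds (separate scales for intercept and
    ##     slope offsets)
    if (quint) {
      for (fld in c("q_sd_int", "q_sd_slope")) {
        cur <- state[[fld]]
        prop <- cur * exp(stats::rnorm(1, 0, exp(ls_q)))
        devs <- if (fld == "q_sd_int") state$q_int else state$q_slope
        la <- sum(stats::dnorm(devs, 0, prop, log = TRUE)) + prior_fn(prop) +
          log(prop) -
          sum(stats::dnorm(devs, 0, cur, log = TRUE)) - prior_fn(cur) -
          log(cur)
        ok <- is.finite(la) && log(stats::runif(1)) < la
        if (ok) state[[fld]] <- prop
        if (!in_burn) {
          att["q_sd"] <- att["q_sd"] + 1
          acc["q_sd"] <- acc["q_sd"] + ok
        } else burn_acc["q_sd"] <- burn_acc["q_sd"] + ok
        ls_q <- ls_q + gam * ((ok) - 0.44)
      }
    }

    ## --- observation noise sd (log-scale random walk, Uniform prior)
    if (!fix_tau) {
      eta <- rowSums(md$X * state$country_beta[md$country, , drop = FALSE])
      if (quint) {
        idx <- cbind(md$country, md$quintile)
        eta <- eta + state$q_int[idx] + state$q_slope[idx] * md$X[, "year"]
      }
      ss <- sum((md$y - eta)^2)
      cur <- state$obs_sd
      prop <- cur * exp(stats::rnorm(1, 0, exp(ls_tau)))
      la <- if (prop >= priors$tau_upper) -Inf else {
        (-md$n * log(prop) - ss / (2 * prop^2) + log(prop)) -
          (-md$n * log(cur) - ss / (2 * cur^2) + log(cur))
      }
      ok <- is.finite(la) && log(stats::runif(1)) < la
      if (ok) state$obs_sd <- prop
      if (!in_burn) {
        att["tau"] <- att["tau"] + 1
        acc["tau"] <- acc["tau"] + ok
      } else burn_acc["tau"] <- burn_acc["tau"] + ok
      ls_tau <- ls_tau + gam * ((ok) - 0.44)
    }

    if (!in_burn && (it - cfg$burn_in) %% cfg$thin == 0L) {
      keep_i <- keep_i + 1L
      out[keep_i, ] <- pack_state(state, lay)
    }
  }

  active <- c(region_sd = !fix_rs, global_sd = !fix_gs, tau = !fix_tau,
              q_sd = quint)
  if (cfg$burn_in > 0) {
    for (b in names(active)[active]) {
      if (burn_acc[b] == 0) {
        warning("zero Metropolis acceptance during burn-in for block ", b)
      }
    }
  }
  rate <- ifelse(att > 0, acc / att, NA_real_)
  list(draws = out, acceptance = rate[active])
}

#' Draw from the posterior of the hierarchical trend model
#'
#' Runs the Metropolis-within-Gibbs sampler for `config$chains` chains,
#' discards burn-in and applies thinning. Fully reproducible from
#' `config$seed`.
#'
#' @param md model frame from [build_model_frame()].
#' @param priors an [anc_priors()].
#' @param config an [sampler_config()].
#' @param fixed optional list fixing scale parameters (`region_sd`,
#'   `global_sd`, `obs_sd`) at known values; their Metropolis updates are
#'   skipped. Used for conjugate-oracle validation.
#' @param init optional initial state (default data-driven, see
#'   `init_state`).
#' @return an object of class `anc_draws`: array `draws` indexed
#'   (chain, retained iteration, parameter), `parameter_names`, per-block
#'   Metropolis `acceptance` rates, the `config` and the parameter `layout`.
#' @keywords internal
run_sampler <- function(md, priors, config, fixed = list(), init = NULL,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  lay <- make_layout(md)
  nm <- layout_names(lay)
  chain_fn <- if (engine == "cpp") run_chain_compiled else run_chain
  chains <- lapply(seq_len(config$chains), function(ch) {
    chain_fn(md, priors, config, fixed, init,
             chain_seed = config$seed + 77003L * ch)
  })
  arr <- array(NA_real_, c(config$chains, config$n_retained, length(nm)),
               dimnames = list(NULL, NULL, nm))
  for (ch in seq_along(chains)) arr[ch, , ] <- chains[[ch]]$draws
  accept <- colMeans(do.call(rbind, lapply(chains, `[[`, "acceptance")))
  structure(list(draws = arr, parameter_names = nm, acceptance = accept,
                 config = config, layout = lay),
            class = "anc_draws")
}

#' @export
print.anc_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior draws:", d[1], "chain(s) x", d[2], "retained iterations x",
      d[3], "parameters\n")
  cat("Metropolis acceptance:",
      paste(names(x$acceptance), signif(x$acceptance, 2), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Stack chains of posterior draws into a matrix
#' @param x an `anc_draws` object.
#' @param ... unused.
#' @return matrix (chains * retained iterations) x parameters.
#' @export
as.matrix.anc_draws <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(aperm(x$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(out) <- x$parameter_names
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF per parameter: with within-chain variance `W` and
#' between-chain variance `B`, the point estimate is
#' `sqrt(((n-1)/n * W + B/n) / W)`; the upper limit applies the standard
#' 97.5% F-quantile correction to the between-chain component. Requires at
#' least 2 chains and 10 retained draws per chain. Parameters with zero
#' within-chain variance in all chains (e.g. parameters held fixed) are
#' reported as 1.
#'
#' @param draws an `anc_draws` object, or a (chain x iteration x parameter)
#'   array, or an iteration x chain matrix for a single parameter.
#' @return data.frame with columns `parameter`, `point`, `upper`.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "anc_draws")) draws <- draws$draws
  if (is.matrix(draws)) {
    draws <- array(t(draws), c(ncol(draws), nrow(draws), 1),
                   dimnames = list(NULL, NULL, "parameter"))
  }
  m <- dim(draws)[1]; n <- dim(draws)[2]
  if (m < 2) stop("Gelman-Rubin diagnostics need at least 2 chains")
  if (n < 10) stop("Gelman-Rubin diagnostics need at least 10 retained draws")
  pn <- dimnames(draws)[[3]]
  res <- t(vapply(seq_len(dim(draws)[3]), function(i) {
    x <- t(draws[, , i])                # n x m
    means <- colMeans(x)
    s2 <- apply(x, 2, stats::var)
    W <- mean(s2)
    B <- n * stats::var(means)
    if (!isTRUE(W > 0)) return(c(point = 1, upper = 1))
    point <- sqrt(((n - 1) / n * W + B / n) / W)
    upper <- if (B / W < 1e-12 || m < 2) point else {
      var_w <- stats::var(s2)
      df_w <- if (isTRUE(var_w > 0)) 2 * W^2 / (var_w / m) else Inf
      sqrt((n - 1) / n +
             (m + 1) / (m * n) * (B / W) * stats::qf(0.975, m - 1, df_w))
    }
    c(point = point, upper = max(upper, point))
  }, numeric(2)))
  data.frame(parameter = if (is.null(pn)) seq_len(nrow(res)) else pn,
             point = res[, "point"], upper = res[, "upper"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Equal-tailed credible interval from posterior samples
#'
#' Empirical percentile interval (linear-interpolation quantiles, R type 7).
#' For a 95% interval these are the 2.5 and 97.5 percentiles.
#'
#' @param samples numeric vector of draws.
#' @param level interval mass, default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
credible_interval <- function(samples, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(samples) < ceiling(2 / (1 - level))) {
    stop("too few samples (", length(samples), ") for a ",
         round(100 * level), "% interval")
  }
  q <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Effective sample size of a (possibly autocorrelated) draw sequence
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial positive-sequence rule on lag pairs.
#'
#' @param x numeric vector of draws.
#' @return estimated effective sample size.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  max_lag <- min(n - 2L, 2000L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with deviance `D(theta) = -2 log L(theta)`, `Dbar` the
#' posterior mean deviance and `pD = Dbar - D(posterior mean of theta)`.
#'
#' @param object posterior draws: an [anc_trend()] fit, or a draw matrix with
#'   a log-likelihood function.
#' @param ... passed to methods.
#' @return list with `dic`, `dbar`, `pd`.
#' @export
dic <- function(object, ...) UseMethod("dic")

#' @rdname dic
#' @param loglik for the default method, `function(par)` returning the
#'   log-likelihood of one parameter vector (a row of `object`).
#' @export
dic.default <- function(object, loglik, ...) {
  draws <- as.matrix(object)
  if (!nrow(draws)) stop("no draws")
  dev <- -2 * apply(draws, 1, loglik)
  dbar <- mean(dev)
  dhat <- -2 * loglik(colMeans(draws))
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, pd = pd)
}

# log-likelihood of every retained draw of a fit (vectorized over draws)
draws_loglik <- function(draws, md) {
  mat <- as.matrix(draws)
  lay <- draws$layout
  nd <- nrow(mat)
  K <- length(lay$countries)
  eta <- matrix(0, nd, md$n)
  for (cc in seq_along(lay$coefs)) {
    cols <- mat_names("beta_country", lay$countries, lay$coefs[cc])
    cb <- mat[, cols, drop = FALSE]            # nd x K
    eta <- eta + cb[, md$country, drop = FALSE] *
      rep(md$X[, cc], each = nd)
  }
  if (lay$quint) {
    for (q in 1:5) {
      sel <- which(md$quintile == q)
      if (!length(sel)) next
      qi <- mat[, mat_names("q_int", lay$countries, paste0("Q", q)), drop = FALSE]
      qs <- mat[, mat_names("q_slope", lay$countries, paste0("Q", q)), drop = FALSE]
      eta[, sel] <- eta[, sel] + qi[, md$country[sel], drop = FALSE] +
        qs[, md$country[sel], drop = FALSE] * rep(md$X[sel, "year"], each = nd)
    }
  }
  tau <- mat[, "tau"]
  resid2 <- (rep(md$y, each = nd) - eta)^2
  -md$n / 2 * log(2 * pi) - md$n * log(tau) - rowSums(resid2) / (2 * tau^2)
}
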