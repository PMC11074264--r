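#' Construct a Gaussian fuzzy rule bank
#'
#' @param means numeric matrix `[n_inputs x n_rules]` of membership centres.
#' @param sigmas positive matrix of the same shape; entries below `sigmaMin`
#'   are rejected.
#' @param consequents optional zero-order TSK consequent weights, one per
#'   rule.
#' @param sigmaMin positive floor on standard deviations (default 1e-3).
#' @return a validated \linkS4class{FuzzyRuleBank}.
#' @examples
#' bank <- fuzzyRuleBank(matrix(0, 2, 1), matrix(1, 2, 1))
#' fuzzify(c(1, 1), bank)           # exp(-1/2)
#' @export
fuzzyRuleBank <- function(means, sigmas, consequents = numeric(),
                          sigmaMin = 1e-3) {
  new("FuzzyRuleBank", means = as.matrix(means), sigmas = as.matrix(sigmas),
      consequents = as.numeric(consequents), sigmaMin = as.numeric(sigmaMin))
}

#' Random seeded rule bank
#'
#' Means drawn `Normal(0, 1)` (matched to standardized features), sigmas 1,
#' optional consequents `Normal(0, 0.1)`.
#'
#' @param nInputs,nRules bank shape.
#' @param withConsequents draw TSK consequents too.
#' @param seed integer seed.
#' @inheritParams fuzzyRuleBank
#' @return a \linkS4class{FuzzyRuleBank}.
#' @export
randomRuleBank <- function(nInputs, nRules, withConsequents = FALSE,
                           sigmaMin = 1e-3, seed = 1L) {
  withLocalSeed(seed, {
    m <- matrix(rnorm(nInputs * nRules), nInputs, nRules)
    w <- if (withConsequents) rnorm(nRules, 0, 0.1) else numeric()
    fuzzyRuleBank(m, matrix(1, nInputs, nRules), w, sigmaMin)
  })
}

setMethod("show", "FuzzyRuleBank", function(object) {
  cat(sprintf("FuzzyRuleBank: %d inputs x %d rules (sigmaMin=%g)%s\n",
              nrow(object@means), ncol(object@means), object@sigmaMin,
              if (length(object@consequents)) ", with TSK consequents" else ""))
})

#' Gaussian membership degree
#'
#' \deqn{\mu(u) = \exp\{-(u - m)^2 / (2\sigma^2)\}}
#' Equals 1 iff `u = m` and is symmetric in `u - m`.
#'
#' @param u crisp input (vectorized).
#' @param m membership centre.
#' @param sigma standard deviation, `>= sigmaMin`.
#' @param sigmaMin positive floor (default 1e-3).
#' @return degree(s) in (0, 1].
#' @examples
#' gaussianMembership(1, 0, 1)   # exp(-1/2)
#' @export
gaussianMembership <- function(u, m, sigma, sigmaMin = 1e-3) {
  stopIfNot(all(sigma >= sigmaMin),
            sprintf("sigma must be >= sigmaMin (%g)", sigmaMin))
  exp(-(u - m)^2 / (2 * sigma^2))
}

# Per-rule exponents e_j = sum_i (x_i - m_ij)^2 / (2 sigma_ij^2) for a
# single input vector.
ruleExponents <- function(x, means, sigmas) {
  colSums((x - means)^2 / (2 * sigmas^2))
}

#' Fuzzify a crisp input vector into rule strengths
#'
#' Singleton fuzzification under Gaussian memberships: each rule `j`
#' accumulates the exponent `e_j = sum_i (x_i - m_ij)^2 / (2 sigma_ij^2)`.
#' With `aggregation = "geometric-mean"` the strength is
#' `exp(-e_j / n_inputs)` — the geometric mean of the per-input membership
#' degrees, which stays in (0, 1] for any input dimension instead of
#' underflowing like the raw product. With `"product-log"` it is the
#' max-shifted product `exp(-(e_j - min_j e_j))`, whose largest strength is
#' always 1. Both are smooth in the inputs and parameters (the shift is
#' piecewise smooth at argmin ties).
#'
#' @param x crisp input vector, length `n_inputs`.
#' @param bank a \linkS4class{FuzzyRuleBank}.
#' @param aggregation `"geometric-mean"` (default) or `"product-log"`.
#' @return rule strengths in (0, 1], length `n_rules`.
#' @export
fuzzify <- function(x, bank, aggregation = c("geometric-mean", "product-log")) {
  aggregation <- match.arg(aggregation)
  stopIfNot(is(bank, "FuzzyRuleBank"), "bank must be a FuzzyRuleBank")
  validObject(bank)
  stopIfNot(length(x) == nrow(bank@means),
            sprintf("x has length %d but the bank expects %d inputs",
                    length(x), nrow(bank@means)))
  e <- ruleExponents(as.numeric(x), bank@means, bank@sigmas)
  if (aggregation == "geometric-mean") exp(-e / length(x))
  else exp(-(e - min(e)))
}

#' Centre-of-gravity defuzzification
#'
#' Maps rule activations `x` to crisp outputs
#' \deqn{\nu_k = \frac{\sum_j C_{kj} x_j}{\sum_j x_j + \epsilon}.}
#' For nonnegative `x` with `sum(x)` well above `eps`, each output lies
#' between the smallest and largest centre of its row, and the output is
#' invariant to positive rescaling of `x`. An all-zero activation vector
#' returns the zero vector (the `eps` guard prevents division by zero).
#'
#' @param x numeric activation vector, length `n_rules`.
#' @param centers numeric matrix `[n_outputs x n_rules]` of output centres.
#' @param eps positive denominator guard (default 1e-9).
#' @return crisp output vector, length `n_outputs`.
#' @examples
#' defuzzify(c(1, 1), matrix(c(0, 4), 1, 2))   # midpoint: 2
#' @export
defuzzify <- function(x, centers, eps = 1e-9) {
  centers <- as.matrix(centers)
  stopIfNot(eps > 0, "eps must be positive")
  stopIfNot(all(is.finite(x)), "x must be finite")
  stopIfNot(length(x) == ncol(centers),
            sprintf("x has length %d but centers has %d columns",
                    length(x), ncol(centers)))
  as.numeric(centers %*% x) / (sum(x) + eps)
}

# Analytic Jacobians of the standalone operators, used by checkGradients()
# and exercised against finite differences in the test-suite.

# fuzzify: returns list(dx [R x D], dm [R x D x R -> per-rule], dsigma).
# Only rule j depends on (m_ij, sigma_ij), except through the product-log
# shift, which couples every rule to the argmin rule.
fuzzifyJacobian <- function(x, bank, aggregation = "geometric-mean") {
  m <- bank@means; s <- bank@sigmas
  D <- nrow(m); R <- ncol(m)
  e <- ruleExponents(x, m, s)
  dif <- x - m                       # D x R
  dedx <- dif / s^2                  # de_j/dx_i, D x R
  dedm <- -dif / s^2
  deds <- -dif^2 / s^3
  if (aggregation == "geometric-mean") {
    st <- exp(-e / D)
    # ds_j/dtheta = -st_j/D * de_j/dtheta
    dx <- -sweep(dedx, 2, st / D, "*")        # D x R: ds_j/dx_i
    dm <- array(0, c(D, R, R))                # ds_r/dm_ij
    dsig <- array(0, c(D, R, R))
    for (j in seq_len(R)) {
      dm[, j, j] <- -st[j] / D * dedm[, j]
      dsig[, j, j] <- -st[j] / D * deds[, j]
    }
  } else {
    jstar <- which.min(e)
    st <- exp(-(e - e[jstar]))
    # ds_r/dtheta = st_r * (-de_r/dtheta + de_jstar/dtheta)
    dx <- matrix(0, D, R)
    for (r in seq_len(R))
      dx[, r] <- st[r] * (-dedx[, r] + dedx[, jstar])
    dm <- array(0, c(D, R, R))
    dsig <- array(0, c(D, R, R))
    for (r in seq_len(R)) {
      dm[, r, r] <- dm[, r, r] - st[r] * dedm[, r]
      dm[, jstar, r] <- dm[, jstar, r] + st[r] * dedm[, jstar]
      dsig[, r, r] <- dsig[, r, r] - st[r] * deds[, r]
      dsig[, jstar, r] <- dsig[, jstar, r] + st[r] * deds[, jstar]
    }
  }
  list(strengths = st, dx = dx, dm = dm, dsigma = dsig)
}

# defuzzify: dv_k/dx_j = (C_kj - v_k)/Dn; dv_k/dC_kj = x_j/Dn.
defuzzifyJacobian <- function(x, centers, eps = 1e-9) {
  Dn <- sum(x) + eps
  v <- as.numeric(centers %*% x) / Dn
  dx <- sweep(centers, 1, v, "-") / Dn     # K x R
  dC <- matrix(x / Dn, nrow(centers), length(x), byrow = TRUE)
  list(value = v, dx = dx, dC = dC)
}

#' Finite-difference gradient verification of the fuzzy operators
#'
#' Builds a random small instance of the chosen operator, computes its
#' analytic Jacobian with respect to every input and parameter, compares it
#' against central finite differences with step `h`, and returns the
#' maximum deviation over all entries, normalized by the largest
#' finite-difference gradient magnitude.
#'
#' @param operator `"fuzzify"` or `"defuzzify"`.
#' @param nInputs,nRules,nOutputs probe dimensions.
#' @param aggregation rule aggregation for the fuzzify probe.
#' @param h central-difference step, in `[1e-7, 1e-3]`.
#' @param seed integer seed for the probe.
#' @param corrupt internal fault-injection hook: a constant added to the
#'   analytic gradients so the harness can prove it detects broken
#'   gradients. Default 0.
#' @return maximum relative deviation (scalar).
#' @examples
#' checkGradients("fuzzify", nInputs = 5, nRules = 3)
#' @export
checkGradients <- function(operator = c("fuzzify", "defuzzify"),
                           nInputs = 5L, nRules = 3L, nOutputs = 2L,
                           aggregation = "geometric-mean",
                           h = 1e-5, seed = 1L, corrupt = 0) {
  operator <- match.arg(operator)
  stopIfNot(h >= 1e-7 && h <= 1e-3, "h must lie in [1e-7, 1e-3]")
  withLocalSeed(seed, {
    if (operator == "fuzzify") {
      bank <- fuzzyRuleBank(matrix(rnorm(nInputs * nRules), nInputs, nRules),
                            matrix(runif(nInputs * nRules, 0.5, 1.5),
                                   nInputs, nRules))
      x <- rnorm(nInputs)
      jac <- fuzzifyJacobian(x, bank, aggregation)
      f <- function(xv, mv, sv)
        fuzzify(xv, fuzzyRuleBank(mv, sv), aggregation)
      num <- list(dx = matrix(0, nInputs, nRules),
                  dm = array(0, c(nInputs, nRules, nRules)),
                  dsigma = array(0, c(nInputs, nRules, nRules)))
      for (i in seq_len(nInputs)) {
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        num$dx[i, ] <- (f(xp, bank@means, bank@sigmas) -
                          f(xm, bank@means, bank@sigmas)) / (2 * h)
        for (j in seq_len(nRules)) {
          mp <- bank@means; mp[i, j] <- mp[i, j] + h
          mm <- bank@means; mm[i, j] <- mm[i, j] - h
          num$dm[i, j, ] <- (f(x, mp, bank@sigmas) - f(x, mm, bank@sigmas)) / (2 * h)
          sp <- bank@sigmas; sp[i, j] <- sp[i, j] + h
          sm <- bank@sigmas; sm[i, j] <- sm[i, j] - h
          num$dsigma[i, j, ] <- (f(x, bank@means, sp) - f(x, bank@means, sm)) / (2 * h)
        }
      }
      ana <- c(jac$dx, jac$dm, jac$dsigma) + corrupt
      fd <- c(num$dx, num$dm, num$dsigma)
    } else {
      centers <- matrix(rnorm(nOutputs * nRules), nOutputs, nRules)
      x <- runif(nRules, 0.2, 1)
      jac <- defuzzifyJacobian(x, centers)
      num <- list(dx = matrix(0, nOutputs, nRules),
                  dC = array(0, c(nOutputs, nRules)))
      numdC <- array(0, c(nOutputs, nRules, nOutputs))
      for (j in seq_len(nRules)) {
        xp <- x; xp[j] <- x[j] + h
        xm <- x; xm[j] <- x[j] - h
        num$dx[, j] <- (defuzzify(xp, centers) - defuzzify(xm, centers)) / (2 * h)
        for (k in seq_len(nOutputs)) {
          cp <- centers; cp[k, j] <- cp[k, j] + h
          cm <- centers; cm[k, j] <- cm[k, j] - h
          numdC[k, j, ] <- (defuzzify(x, cp) - defuzzify(x, cm)) / (2 * h)
        }
      }
      # dC_kj only moves output k; off-output entries must be ~0
      anadC <- array(0, c(nOutputs, nRules, nOutputs))
      for (k in seq_len(nOutputs)) anadC[k, , k] <- jac$dC[k, ]
      ana <- c(jac$dx, anadC) + corrupt
      fd <- c(num$dx, numdC)
    }
    scale <- max(abs(fd), 1e-8)
    max(abs(ana - fd)) / scale
  })
}
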