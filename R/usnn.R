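#' @include AllClasses.R AllGenerics.R stimulation.R optim-lse.R
NULL

#' Construct a generator-network configuration
#'
#' @param hiddenWidths hidden-layer sizes (default three layers of 64).
#' @param epochs training steps (default 1000; multi-target studies use 2000).
#' @param learningRate Adam step size (default 1e-3, Adam's conventional
#'   default; moment decays are the library defaults 0.9/0.999).
#' @param seed RNG seed for weight initialization.
#' @param mode `"tTIS"` (two frequency channels) or `"tACS"` (one).
#' @param slope sigmoid slope of the smooth mis-area (default 1).
#' @param normalizationMode `"per_frequency"` or `"joint"` safety limits.
#' @param modulationForm training modulation form. The default
#'   `"envelope_min"` is the non-negative beat envelope `2*min(|a|,|b|)`:
#'   the network's field layers pass through an absolute-value activation
#'   before the modulation layer, and on those amplitudes the
#'   difference-of-absolutes expression reduces to the envelope. The raw
#'   `"signed_difference"` form is retained but can make the ratio loss
#'   unbounded below where the two fields have opposite signs.
#' @return a validated [UsnnConfig].
#' @export
UsnnConfig <- function(hiddenWidths = c(64L, 64L, 64L), epochs = 1000L,
                       learningRate = 1e-3, seed = 1L, mode = "tTIS",
                       slope = 1, normalizationMode = "per_frequency",
                       modulationForm = "envelope_min") {
  new("UsnnConfig", hiddenWidths = as.integer(hiddenWidths),
      epochs = as.integer(epochs), learningRate = learningRate,
      seed = as.integer(seed), mode = mode, slope = slope,
      normalizationMode = normalizationMode, modulationForm = modulationForm)
}

## ---- generator network: constant unit input -> hidden (linear, ReLU,
## ---- layer norm) stack -> linear electrode layer; hand-written reverse mode

.initNet <- function(hiddenWidths, nOut) {
  dims <- c(1L, hiddenWidths, nOut)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    fanIn <- dims[i]
    W <- matrix(rnorm(dims[i + 1L] * fanIn) * sqrt(2 / fanIn), dims[i + 1L], fanIn)
    layers[[i]] <- list(W = W, b = numeric(dims[i + 1L]))
    if (i < length(layers)) {            # hidden layers carry layer-norm params
      layers[[i]]$g <- rep(1, dims[i + 1L])
      layers[[i]]$c <- numeric(dims[i + 1L])
    }
  }
  layers
}

.LN_EPS <- 1e-5

.netForward <- function(net) {
  x <- 1
  cache <- vector("list", length(net))
  for (i in seq_along(net)) {
    ly <- net[[i]]
    z <- as.numeric(ly$W %*% x) + ly$b
    if (i < length(net)) {
      a <- pmax(z, 0)
      mu <- mean(a)
      v <- mean((a - mu)^2)
      sdv <- sqrt(v + .LN_EPS)
      xhat <- (a - mu) / sdv
      y <- ly$g * xhat + ly$c
      cache[[i]] <- list(x = x, z = z, a = a, sdv = sdv, xhat = xhat)
      x <- y
    } else {
      cache[[i]] <- list(x = x)
      x <- z
    }
  }
  list(out = x, cache = cache)
}

.netBackward <- function(net, cache, dOut) {
  grads <- vector("list", length(net))
  dy <- dOut
  for (i in rev(seq_along(net))) {
    ly <- net[[i]]
    cc <- cache[[i]]
    if (i < length(net)) {
      dg <- dy * cc$xhat
      dc <- dy
      dxhat <- dy * ly$g
      H <- length(dxhat)
      da <- (dxhat - mean(dxhat) - cc$xhat * mean(dxhat * cc$xhat)) / cc$sdv
      dz <- da * (cc$z > 0)
      grads[[i]] <- list(W = dz %o% cc$x, b = dz, g = dg, c = dc)
    } else {
      dz <- dy
      grads[[i]] <- list(W = dz %o% cc$x, b = dz)
    }
    if (i > 1L) dy <- as.numeric(t(ly$W) %*% dz)
  }
  grads
}

## forward + gradient of the safety normalization n = gamma(v) * v for one
## zero-sum channel; returns scale, branch info for the backward pass
.normForward <- function(v) {
  m <- max(abs(v))
  if (m == 0) stop("degenerate montage: generator emitted an all-zero channel")
  S <- sum(abs(v))
  if (2 * S / m <= 8) {
    list(gamma = 2 / m, branch = "max", jmax = which.max(abs(v)), m = m, S = S)
  } else {
    list(gamma = 8 / S, branch = "sum", jmax = which.max(abs(v)), m = m, S = S)
  }
}

## backward through n = gamma * v: gv = gamma * gn + (gn . v) * dgamma/dv
.normBackward <- function(v, nf, gn) {
  dot <- sum(gn * v)
  gv <- nf$gamma * gn
  if (nf$branch == "max") {
    gv[nf$jmax] <- gv[nf$jmax] - dot * 2 / nf$m^2 * sign(v[nf$jmax])
  } else {
    gv <- gv - dot * 8 * sign(v) / nf$S^2
  }
  gv
}

## loss forward + gradient with respect to the modulation vector; returns
## zero gradients (not NaN) in the saturated PR = Inf regime
.lossGradModulation <- function(Mod, tidx, slope) {
  N <- length(Mod)
  Tn <- length(tidx)
  nt <- setdiff(seq_len(N), tidx)
  if (length(nt) == 0L) {
    ## whole surface is the target: nothing to mis-stimulate, loss floor
    return(list(loss = 0, grad = numeric(N), PR = Inf, CR = 1, MRs = 0))
  }
  mu <- mean(Mod[tidx])
  sig <- 1 / (1 + exp(-slope * (Mod[nt] - mu)))
  A <- sum(sig)
  MRs <- A / Tn
  pI <- tidx[which.max(Mod[tidx])]
  qI <- nt[which.max(Mod[nt])]
  p <- Mod[pI]; q <- Mod[qI]
  St <- sum(Mod[tidx]); S <- sum(Mod)
  PR <- p / q
  CR <- (N * St) / (Tn * S)
  loss <- MRs / (PR * CR)
  g <- numeric(N)
  if (is.finite(loss)) {
    dMRs <- 1 / (PR * CR)
    dPR <- -MRs / (PR^2 * CR)
    dCR <- -MRs / (PR * CR^2)
    w <- slope * sig * (1 - sig)
    g[nt] <- g[nt] + dMRs * w / Tn
    g[tidx] <- g[tidx] - dMRs * sum(w) / Tn^2
    if (is.finite(PR) && q != 0) {
      g[pI] <- g[pI] + dPR / q
      g[qI] <- g[qI] - dPR * p / q^2
    }
    if (is.finite(CR) && S != 0) {
      g <- g + dCR * (-CR / S)
      g[tidx] <- g[tidx] + dCR * N / (Tn * S)
    }
  }
  list(loss = loss, grad = g, PR = PR, CR = CR, MRs = MRs)
}

## full differentiable physics pipeline: electrode-layer output ->
## zero-sum expansion -> safety normalization -> fields -> modulation ->
## three-ratio loss; returns loss, d loss / d output, normalized currents
.usnnPipeline <- function(o, env) {
  Fn <- env$F
  if (env$mode == "tTIS") {
    c1 <- o[seq_len(Fn)]; c2 <- o[Fn + seq_len(Fn)]
  } else {
    c1 <- o; c2 <- o
  }
  v1 <- expandCurrents(c1, env$ref)
  v2 <- expandCurrents(c2, env$ref)
  if (env$normMode == "per_frequency") {
    nf1 <- .normForward(v1); nf2 <- .normForward(v2)
    n1 <- nf1$gamma * v1; n2 <- nf2$gamma * v2
  } else {
    vc <- c(v1, v2)
    nfj <- .normForward(vc)
    n1 <- nfj$gamma * v1; n2 <- nfj$gamma * v2
  }
  f1 <- as.numeric(env$E %*% n1[-env$ref])
  f2 <- if (env$mode == "tTIS") as.numeric(env$E %*% n2[-env$ref]) else f1
  Mod <- if (env$mode == "tACS") {
    2 * abs(f1)
  } else if (env$form == "signed_difference") {
    abs(f1 + f2) - abs(f1 - f2)
  } else {
    2 * pmin(abs(f1), abs(f2))
  }
  lg <- .lossGradModulation(Mod, env$tidx, env$slope)
  g <- lg$grad

  if (env$mode == "tACS") {
    gf1 <- g * 2 * sign(f1)
    gf2 <- NULL
  } else if (env$form == "signed_difference") {
    s1 <- sign(f1 + f2); s2 <- sign(f1 - f2)
    gf1 <- g * (s1 - s2)
    gf2 <- g * (s1 + s2)
  } else {
    takeF1 <- abs(f1) <= abs(f2)
    gf1 <- ifelse(takeF1, 2 * sign(f1), 0) * g
    gf2 <- ifelse(takeF1, 0, 2 * sign(f2)) * g
  }

  gn1 <- numeric(length(v1)); gn2 <- numeric(length(v2))
  gn1[-env$ref] <- as.numeric(crossprod(env$E, gf1))
  if (env$mode == "tTIS") gn2[-env$ref] <- as.numeric(crossprod(env$E, gf2))

  if (env$normMode == "per_frequency") {
    gv1 <- .normBackward(v1, nf1, gn1)
    gv2 <- if (env$mode == "tTIS") .normBackward(v2, nf2, gn2) else NULL
  } else {
    gvc <- .normBackward(c(v1, v2), nfj, c(gn1, gn2))
    gv1 <- gvc[seq_along(v1)]
    gv2 <- gvc[length(v1) + seq_along(v2)]
  }
  gc1 <- gv1[-env$ref] - gv1[env$ref]
  do <- if (env$mode == "tTIS") {
    gc2 <- gv2[-env$ref] - gv2[env$ref]
    c(gc1, gc2)
  } else if (env$normMode == "joint") {
    gc2 <- gv2[-env$ref] - gv2[env$ref]
    gc1 + gc2
  } else {
    gc1
  }
  list(loss = lg$loss, dOut = do, n1 = n1, n2 = n2,
       PR = lg$PR, CR = lg$CR, MRs = lg$MRs)
}

.adamInit <- function(net) {
  lapply(net, function(ly) lapply(ly, function(p) {
    list(m = p * 0, v = p * 0)
  }))
}

.adamStep <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      net[[i]][[nm]] <- net[[i]][[nm]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

#' Unsupervised generator-network montage optimization
#'
#' Trains a small generator network to emit electrode currents that maximize
#' focal beat modulation at the target. The generator takes a constant unit
#' input (no data: the optimization is unsupervised), passes it through
#' fully connected hidden layers (linear map, ReLU, layer normalization) and
#' a linear electrode layer with one output per free electrode and frequency
#' channel. Everything downstream is fixed physics with no trainable
#' weights: outputs are expanded to zero-sum current vectors, safety
#' normalized inside the computation graph (subgradients at the piecewise
#' max/branch points), mapped to fields by the lead-field matrix, combined
#' into the beat modulation, and scored by the smooth three-ratio loss,
#' which is backpropagated to the generator weights and minimized with Adam.
#'
#' The minimum-loss iterate (not the last) is returned. If the generator
#' emits an all-zero pattern at initialization it is re-initialized once
#' with `seed + 1`; a NaN loss aborts with a diagnostic. Training is
#' deterministic given the configuration: the only randomness is the seeded
#' weight initialization.
#'
#' @param leadfield a [LeadField].
#' @param target a [TargetSpec].
#' @param config a [UsnnConfig].
#' @return an [OptimizationResult]; `lossHistory` has one training-form loss
#'   per epoch and `evalCalls` equals `epochs`.
#' @export
#' @examples
#' lf <- generateRandomLeadField(n_nodes = 60, n_electrodes = 8, seed = 3)
#' tg <- selectDepthTarget(lf, 2, k = 6)
#' res <- usnnOptimize(lf, tg, UsnnConfig(epochs = 50L, seed = 3L))
#' finalMetrics(res)
usnnOptimize <- function(leadfield, target, config = UsnnConfig()) {
  stopifnot(is(leadfield, "LeadField"), is(target, "TargetSpec"),
            is(config, "UsnnConfig"))
  validObject(config)
  E <- lfMatrix(leadfield)
  lay <- electrodeLayout(leadfield)
  Fn <- ncol(E)
  env <- list(E = E, ref = lay@referenceIndex, F = Fn,
              tidx = targetNodes(target), slope = config@slope,
              mode = config@mode, form = config@modulationForm,
              normMode = config@normalizationMode)
  nOut <- if (config@mode == "tTIS") 2L * Fn else Fn

  buildNet <- function(seed) {
    set.seed(seed)
    .initNet(config@hiddenWidths, nOut)
  }
  net <- buildNet(config@seed)
  fw <- .netForward(net)
  if (max(abs(fw$out)) == 0) {
    net <- buildNet(config@seed + 1L)
    fw <- .netForward(net)
    if (max(abs(fw$out)) == 0) {
      stop("degenerate generator: all-zero output after re-initialization")
    }
  }

  state <- .adamInit(net)
  hist <- numeric(config@epochs)
  best <- list(loss = Inf, n1 = NULL, n2 = NULL)
  for (epoch in seq_len(config@epochs)) {
    if (epoch > 1L) fw <- .netForward(net)
    pp <- .usnnPipeline(fw$out, env)
    if (is.nan(pp$loss)) {
      stop(sprintf(
        "NaN loss at epoch %d (learning rate %g, slope %g): modulation may be identically zero; lower the learning rate or slope",
        epoch, config@learningRate, config@slope))
    }
    hist[epoch] <- pp$loss
    if (pp$loss < best$loss) {
      best <- list(loss = pp$loss, n1 = pp$n1, n2 = pp$n2)
    }
    grads <- .netBackward(net, fw$cache, pp$dOut)
    upd <- .adamStep(net, grads, state, config@learningRate, epoch)
    net <- upd$net
    state <- upd$state
  }

  pattern <- new("CurrentPattern", f1Currents = best$n1, f2Currents = best$n2,
                 stage = "I", nominalFrequencies = c(2000, 2010))
  metrics <- evaluatePattern(leadfield, pattern, target, slope = config@slope)
  new("OptimizationResult", pattern = pattern, lossHistory = hist,
      finalMetrics = metrics, seed = config@seed,
      evalCalls = config@epochs,
      wallInfo = sprintf("usnn %s: %d epochs, widths %s", config@mode,
                         config@epochs,
                         paste(config@hiddenWidths, collapse = "x")))
}
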