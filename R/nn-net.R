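# Network engine. An ArchSpec is compiled into a flat list of primitive
# nodes (conv unit, head conv, add, concat, upsample, maxpool, sa) joined by
# `from` edges; forward keeps every node output, backward walks the graph in
# reverse accumulating gradients. Parameters live in per-node named lists so
# the whole network is a plain, serializable R object.

kaimingInit <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)), c(kh, kw, cin, cout))
}

nodeConv <- function(from, cin, cout, k = 1L, stride = 1L, act = TRUE) {
  pad <- (k - 1L) %/% 2L
  if (k == 6L) pad <- 2L   # stem conv of the v6-style backbone
  list(op = "conv", from = from, k = k, stride = stride, pad = pad, act = act,
       params = list(w = kaimingInit(k, k, cin, cout),
                     gamma = rep(1, cout), beta = rep(0, cout)),
       stats = list(rmean = rep(0, cout), rvar = rep(1, cout)),
       cout = cout)
}

nodeHead <- function(from, cin, cout, bias_obj = -4.5, na = 3L, nc = 2L) {
  b <- rep(0, cout)
  per <- cout / na
  for (a in seq_len(na)) b[(a - 1) * per + 5L] <- bias_obj
  list(op = "head", from = from, k = 1L, stride = 1L, pad = 0L,
       params = list(w = kaimingInit(1L, 1L, cin, cout) * 0.1, b = b),
       cout = cout)
}

nodeSimple <- function(op, from, cout) list(op = op, from = from, cout = cout)

nodeSA <- function(from, channels, groups) {
  list(op = "sa", from = from, groups = groups,
       params = saParams(channels, groups), cout = channels)
}

# expand one C3 stage (CSP bottleneck with n inner blocks) into primitive
# nodes; returns list(nodes, out_index) with indices relative to `base`.
expandC3 <- function(nodes, from, cin, cout, n, shortcut) {
  ch <- cout %/% 2L
  add <- function(nd) { nodes[[length(nodes) + 1L]] <<- nd; length(nodes) }
  i_cv1 <- add(nodeConv(from, cin, ch, 1L))
  cur <- i_cv1
  for (b in seq_len(n)) {
    i_a <- add(nodeConv(cur, ch, ch, 1L))
    i_b <- add(nodeConv(i_a, ch, ch, 3L))
    cur <- if (shortcut) add(nodeSimple("add", c(cur, i_b), ch)) else i_b
  }
  i_cv2 <- add(nodeConv(from, cin, ch, 1L))
  i_cat <- add(nodeSimple("concat", c(cur, i_cv2), 2L * ch))
  i_cv3 <- add(nodeConv(i_cat, 2L * ch, cout, 1L))
  list(nodes = nodes, out = i_cv3)
}

expandSPPF <- function(nodes, from, cin, cout, k) {
  ch <- cin %/% 2L
  add <- function(nd) { nodes[[length(nodes) + 1L]] <<- nd; length(nodes) }
  i_cv1 <- add(nodeConv(from, cin, ch, 1L))
  i_p1 <- add(c(nodeSimple("maxpool", i_cv1, ch), k = k))
  i_p2 <- add(c(nodeSimple("maxpool", i_p1, ch), k = k))
  i_p3 <- add(c(nodeSimple("maxpool", i_p2, ch), k = k))
  i_cat <- add(nodeSimple("concat", c(i_cv1, i_p1, i_p2, i_p3), 4L * ch))
  i_cv2 <- add(nodeConv(i_cat, 4L * ch, cout, 1L))
  list(nodes = nodes, out = i_cv2)
}

#' Build a runnable detector from an architecture specification
#'
#' Compiles the stage list of an [ArchSpec][ArchSpec-class] into a flat
#' primitive graph with initialized parameters. The result is a plain list
#' (class `"podrotDetector"`) holding the node list, the indices of the three
#' detection-head outputs, and the anchor/stride/class metadata needed for
#' decoding.
#'
#' @param spec an `ArchSpec`, e.g. from [yoloArchSpec()].
#' @param seed integer seed for weight initialization.
#' @return a `podrotDetector` object.
#' @export
buildDetector <- function(spec, seed = 0L) {
  stopifnot(is(spec, "ArchSpec"))
  withSeed(seed, {
    nodes <- list()
    stage_out <- integer(length(spec@stages))  # node index of each stage output
    na <- nrow(spec@anchors[[1]])
    no <- na * (5L + spec@numClasses)
    head_idx <- integer(0)
    resolve <- function(from, s) {
      vapply(from, function(f) if (f < 0) stage_out[s + f] else stage_out[f + 1L], 0L)
    }
    chans <- integer(length(spec@stages))
    stage_ch <- function(f, s) if (f < 0) chans[s + f] else chans[f + 1L]
    for (s in seq_along(spec@stages)) {
      st <- spec@stages[[s]]
      if (s == 1L) {
        frm <- 0L; cin <- 3L
      } else {
        frm <- resolve(st$from, s)
        cin <- sum(vapply(st$from, stage_ch, 0L, s = s))
      }
      if (st$kind == "conv") {
        nodes[[length(nodes) + 1L]] <-
          nodeConv(if (s == 1L) 0L else frm, cin, st$channels, st$k, st$stride)
        stage_out[s] <- length(nodes); chans[s] <- st$channels
      } else if (st$kind == "C3") {
        r <- expandC3(nodes, frm, cin, st$channels, st$n %||% 1L,
                      isTRUE(st$shortcut %||% TRUE))
        nodes <- r$nodes; stage_out[s] <- r$out; chans[s] <- st$channels
      } else if (st$kind == "SPPF") {
        r <- expandSPPF(nodes, frm, cin, st$channels, st$k %||% 5L)
        nodes <- r$nodes; stage_out[s] <- r$out; chans[s] <- st$channels
      } else if (st$kind == "SA") {
        nodes[[length(nodes) + 1L]] <- nodeSA(frm, cin, st$groups)
        stage_out[s] <- length(nodes); chans[s] <- cin
      } else if (st$kind == "upsample") {
        nodes[[length(nodes) + 1L]] <- nodeSimple("upsample", frm, cin)
        stage_out[s] <- length(nodes); chans[s] <- cin
      } else if (st$kind == "concat") {
        nodes[[length(nodes) + 1L]] <- nodeSimple("concat", frm, cin)
        stage_out[s] <- length(nodes); chans[s] <- cin
      } else if (st$kind == "detect") {
        for (f in seq_along(frm)) {
          cin_f <- stage_ch(st$from[f], s)
          nodes[[length(nodes) + 1L]] <-
            nodeHead(frm[f], cin_f, no, na = na, nc = spec@numClasses)
          head_idx <- c(head_idx, length(nodes))
        }
        stage_out[s] <- length(nodes); chans[s] <- no
      } else stop("unknown stage kind: ", st$kind)
    }
    structure(list(nodes = nodes, heads = head_idx, spec = spec,
                   anchors = spec@anchors, strides = spec@strides,
                   numClasses = spec@numClasses, inputSize = spec@inputSize),
              class = "podrotDetector")
  })
}

#' @export
print.podrotDetector <- function(x, ...) {
  cat(sprintf("podrot detector ('%s'): %d nodes, %d parameters, input %d\n",
              x$spec@variant, length(x$nodes), countParams(x), x$inputSize))
  invisible(x)
}

#' Number of trainable parameters of a detector
#' @param detector a `podrotDetector`.
#' @export
countParams <- function(detector) {
  sum(vapply(detector$nodes, function(nd)
    if (is.null(nd$params)) 0L else sum(vapply(nd$params, length, 0L)), 0L))
}

# forward pass; input x (H, W, 3, N). Returns list(heads = raw head arrays,
# outs/caches kept when `keep` for backward).
netForward <- function(detector, x, train = FALSE, keep = train) {
  nodes <- detector$nodes
  outs <- vector("list", length(nodes))
  caches <- if (keep) vector("list", length(nodes)) else NULL
  getin <- function(f) if (f == 0L) x else outs[[f]]
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$op == "conv") {
      cf <- convFwd(getin(nd$from), nd$params$w, NULL, nd$stride, nd$pad)
      d4 <- dim(cf$out)
      if (train) {
        mom <- cpp_channel_moments(cf$out)
        mu <- mom$mean
        vr <- pmax(mom$meansq - mu^2, 0)
        m <- d4[1] * d4[2] * d4[4]
        nd$stats$rmean <- (1 - 0.03) * nd$stats$rmean + 0.03 * mu
        nd$stats$rvar <- (1 - 0.03) * nd$stats$rvar +
          0.03 * vr * m / max(1, m - 1)
        nodes[[i]] <- nd
      } else {
        mu <- nd$stats$rmean; vr <- nd$stats$rvar
      }
      istd <- 1 / sqrt(vr + 1e-3)
      outs[[i]] <- cpp_bnact_forward(cf$out, nd$params$gamma, nd$params$beta,
                                     mu, istd, nd$act)
      if (keep) caches[[i]] <- list(conv = cf$cache, z = cf$out,
                                    mu = mu, istd = istd, train = train)
    } else if (nd$op == "head") {
      cf <- convFwd(getin(nd$from), nd$params$w, nd$params$b, 1L, 0L)
      outs[[i]] <- cf$out
      if (keep) caches[[i]] <- list(conv = cf$cache)
    } else if (nd$op == "add") {
      outs[[i]] <- getin(nd$from[1]) + getin(nd$from[2])
    } else if (nd$op == "concat") {
      ins <- lapply(nd$from, getin)
      outs[[i]] <- abindChannels(ins)
      if (keep) caches[[i]] <- vapply(ins, function(a) dim(a)[3], 0L)
    } else if (nd$op == "upsample") {
      uf <- upsample2Fwd(getin(nd$from)); outs[[i]] <- uf$out
      if (keep) caches[[i]] <- uf$cache
    } else if (nd$op == "maxpool") {
      mf <- maxpoolFwd(getin(nd$from), nd$k); outs[[i]] <- mf$out
      if (keep) caches[[i]] <- mf$cache
    } else if (nd$op == "sa") {
      sf <- saFwd(getin(nd$from), nd$params, nd$groups)
      outs[[i]] <- sf$out
      if (keep) caches[[i]] <- sf$cache
    }
  }
  list(heads = outs[detector$heads], outs = outs, caches = caches,
       nodes = nodes)
}

abindChannels <- function(arrs) {
  d1 <- dim(arrs[[1]])
  ctot <- sum(vapply(arrs, function(a) dim(a)[3], 0L))
  out <- array(0, c(d1[1], d1[2], ctot, d1[4]))
  at <- 0L
  for (a in arrs) {
    ca <- dim(a)[3]
    out[, , at + seq_len(ca), ] <- a
    at <- at + ca
  }
  out
}

# backward pass. head_grads: list of gradients matching fw$heads.
# Returns list of per-node parameter gradient lists.
netBackward <- function(detector, fw, head_grads) {
  nodes <- fw$nodes
  douts <- vector("list", length(nodes))
  pgrads <- vector("list", length(nodes))
  for (k in seq_along(detector$heads))
    douts[[detector$heads[k]]] <- head_grads[[k]]
  addgrad <- function(i, g) {
    if (i == 0L) return(invisible())
    douts[[i]] <<- if (is.null(douts[[i]])) g else douts[[i]] + g
  }
  for (i in rev(seq_along(nodes))) {
    dy <- douts[[i]]
    if (is.null(dy)) next
    nd <- nodes[[i]]; cc <- fw$caches[[i]]
    if (nd$op == "conv") {
      bb <- cpp_bnact_backward(dy, cc$z, nd$params$gamma, nd$params$beta,
                               cc$mu, cc$istd, nd$act, cc$train)
      cb <- convBwd(bb$dx, cc$conv)
      pgrads[[i]] <- list(w = cb$dw, gamma = bb$dgamma, beta = bb$dbeta)
      addgrad(nd$from, cb$dx)
    } else if (nd$op == "head") {
      cb <- convBwd(dy, cc$conv)
      pgrads[[i]] <- list(w = cb$dw, b = cb$db)
      addgrad(nd$from, cb$dx)
    } else if (nd$op == "add") {
      addgrad(nd$from[1], dy); addgrad(nd$from[2], dy)
    } else if (nd$op == "concat") {
      at <- 0L
      for (k in seq_along(nd$from)) {
        ck <- cc[k]
        addgrad(nd$from[k], dy[, , at + seq_len(ck), , drop = FALSE])
        at <- at + ck
      }
    } else if (nd$op == "upsample") {
      addgrad(nd$from, upsample2Bwd(dy, cc))
    } else if (nd$op == "maxpool") {
      addgrad(nd$from, maxpoolBwd(dy, cc))
    } else if (nd$op == "sa") {
      sb <- saBwd(dy, cc, nd$params)
      pgrads[[i]] <- sb$grads
      addgrad(nd$from, sb$dx)
    }
    douts[[i]] <- NULL   # free
  }
  pgrads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate an expression with a temporary RNG seed, restoring caller state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
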