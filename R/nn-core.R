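# Minimal neural-network primitives: activations, initializers and an Adam
# optimizer over arbitrarily nested lists of parameter matrices. All
# randomness goes through R's RNG so runs are reproducible from one seed.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

uniform_init <- function(n_in, n_out, scale) {
  matrix(runif(n_in * n_out, -scale, scale), n_in, n_out)
}

adam_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

# params and grads share one nesting structure; returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
           v = purrr::map(out, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
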