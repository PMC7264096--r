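# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

test_model <- function(asym = 0) {
  key <- paste0("model_", asym)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_jaw_model(seed = 1, asymmetry_scale = asym)
  .fixture_env[[key]]
}

test_envelope <- function(asym = 0) {
  key <- paste0("env_", asym)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- compute_envelope(test_model(asym))
  .fixture_env[[key]]
}

# a custom minimal jaw model built by hand (bypasses the generator): a
# bilateral muscle pair plus optional ligaments, for closed-form oracles
toy_jaw_model <- function(anchors = rbind(c(-30, 0, 40), c(30, 0, 40)),
                          f_max = c(40, 40), l_opt = NULL, w_len = 0.56,
                          k_passive = c(0.05, 0.05), mass = 0.2,
                          damping = 0.01, gravity = 9.81,
                          ligaments = FALSE) {
  n <- nrow(anchors)
  rest_len <- sqrt(rowSums(anchors^2))
  if (is.null(l_opt)) l_opt <- rest_len
  mus <- data.frame(
    name = if (n > 0) paste0(rep(c("LX", "RX"), length.out = n),
                             seq_len(n)) else character(),
    side = rep(c("left", "right"), length.out = n),
    pair_id = rep(seq_len(max(1, ceiling(n / 2))), each = 2)[seq_len(n)],
    role = rep("elevator", n), f_max = f_max, l_opt = l_opt,
    v_max = 8 * l_opt,
    w_len = rep(w_len, length.out = n),
    k_passive = k_passive,
    ox = anchors[, 1], oy = anchors[, 2], oz = anchors[, 3],
    stringsAsFactors = FALSE)
  lig <- if (ligaments)
    data.frame(side = c("left", "right"), ax = c(-40, 40), ay = c(-60, -60),
               az = c(25, 25), rest_length = sqrt(40^2 + 60^2 + 25^2),
               slack_offset = 7.5, elastic_modulus = 2.45,
               cross_section = 30)
  else
    data.frame(side = character(), ax = numeric(), ay = numeric(),
               az = numeric(), rest_length = numeric(),
               slack_offset = numeric(), elastic_modulus = numeric(),
               cross_section = numeric())
  structure(list(muscles = mus, ligaments = lig, mass = mass,
                 gravity = gravity, rest_position = c(0, 0, 0),
                 asymmetry_scale = 0, seed = 0L, a_hill = 0.25,
                 fv_cap = 1.5, damping = damping),
            class = "jaw_model")
}

# free point mass: no muscles, no ligaments
free_point_model <- function(mass = 0.2, damping = 0, gravity = 9.81) {
  toy_jaw_model(anchors = matrix(numeric(0), 0, 3), f_max = numeric(0),
                k_passive = numeric(0), mass = mass, damping = damping,
                gravity = gravity)
}

# tiny SAC agent for update oracles
toy_agent <- function(obs_dim = 4, act_dim = 2, hidden = 8, seed = 11,
                      alpha = 0.3, cap = 64, ...) {
  set.seed(seed)
  sac_agent(obs_dim, act_dim,
            sac_config(hidden = hidden, batch_size = 4, alpha = alpha, ...),
            buffer_capacity = cap)
}

# rollout with a fixed scripted policy function
scripted_policy <- function(action) function(obs) action
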