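#' Read a model configuration from YAML or JSON
#'
#' The configuration either gives the full parameter set
#' (`b1, c1, b2, c2, B1, C1, B2, C2, f`) or the shorthand `B, C, f` (meaning
#' `b_a = B_a = B`, `c_a = C_a = C`: no difference between in-group and
#' out-group interactions). An optional `punishment` block with `gamma` and
#' `beta` (scalars, or per-population `gamma1`/`gamma2`, `beta1`/`beta2`)
#' applies the costly-punishment transformation; an optional scalar
#' `group_pressure` applies [apply_group_pressure()] to every `(B, C)` pair.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [game_params] object with the transformations applied.
#' @export
read_game_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  game_config(cfg)
}

#' Build game parameters from a configuration list
#'
#' @param cfg a named list as described in [read_game_config()].
#' @return A [game_params] object.
#' @export
game_config <- function(cfg) {
  if (is.null(cfg$f)) stop("config must provide the power parameter f")
  full_keys <- c("b1", "c1", "b2", "c2", "B1", "C1", "B2", "C2")
  g <- if (all(full_keys %in% names(cfg))) {
    do.call(game_params, c(cfg[full_keys], list(f = cfg$f)))
  } else if (all(c("B", "C") %in% names(cfg))) {
    game_params(B = cfg$B, C = cfg$C, f = cfg$f)
  } else {
    stop("config must provide either shorthand {B, C, f} or the full ",
         "parameter set {", paste(full_keys, collapse = ", "), ", f}")
  }
  if (!is.null(cfg$punishment)) {
    pb <- cfg$punishment
    pp <- punishment_params(
      gamma1 = pb$gamma1 %||% pb$gamma %||% 0,
      gamma2 = pb$gamma2 %||% pb$gamma %||% 0,
      beta1 = pb$beta1 %||% pb$beta %||% 0,
      beta2 = pb$beta2 %||% pb$beta %||% 0)
    g <- apply_punishment(g, pp, cross = pb$cross %||% "both")
  }
  if (!is.null(cfg$group_pressure)) {
    gp <- cfg$group_pressure
    bc1i <- apply_group_pressure(g$b1, g$c1, gp)
    bc2i <- apply_group_pressure(g$b2, g$c2, gp)
    bc1o <- apply_group_pressure(g$B1, g$C1, gp)
    bc2o <- apply_group_pressure(g$B2, g$C2, gp)
    g <- game_params(f = g$f,
                     b1 = bc1i["B"], c1 = bc1i["C"],
                     b2 = bc2i["B"], c2 = bc2i["C"],
                     B1 = bc1o["B"], C1 = bc1o["C"],
                     B2 = bc2o["B"], C2 = bc2o["C"])
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
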