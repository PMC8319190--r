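## Config schema: JSON tree with sections tumor_transport / systemic_pk /
## geometry / dose. Keys carry unit suffixes (_s, _per_s, _mL, _C);
## unit-less ambiguous fields and unknown keys are rejected at the
## boundary. Time is seconds, volumes mL, rates 1/s package-wide.

.schema <- list(
  tumor_transport = c("v_p", "v_p_sd", "v_v", "v_e", "k_av", "v_e_av",
                      "v_e_av_sd", "TT_s", "TT_sd_s", "PS_per_s",
                      "PS_sd_per_s", "Hct_mv", "F_p_per_s", "EF"),
  systemic_pk = c("V_D_mL", "V_D_sd_mL", "V_p_S_mL", "V_p_S_sd_mL",
                  "k_p_per_s", "k_p_sd_per_s", "k_t_per_s", "k_t_sd_per_s",
                  "k_e_per_s", "k_e_sd_per_s"),
  geometry = c("VT_mL", "VT_sd_mL"),
  dose = c("ID", "form")
)

#' Load a validated parameter bundle from a JSON config
#'
#' Reads the fixed-schema parameter tree (sections `tumor_transport`,
#' `systemic_pk`, `geometry`, optional `dose`), rejects unknown keys with
#' the path to the offending key, and returns the [validate_params()]
#' bundle with derived fields filled in. An `F_p_per_s` override is passed
#' through the bundle's 10% consistency check; an `EF` entry is checked
#' against the derived extraction fraction at printed precision.
#'
#' @param path config file path.
#' @return an `"ivdds_params"` bundle.
#' @export
load_config <- function(path) {
  .chk(file.exists(path), "config file not found: ", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("config parse error: ",
                                           conditionMessage(e), call. = FALSE))
  .chk(is.list(cfg) && length(cfg) > 0, "schema error: empty config")
  unknown_sections <- setdiff(names(cfg), names(.schema))
  .chk(length(unknown_sections) == 0,
       "schema error: unknown section(s): ",
       paste(unknown_sections, collapse = ", "))
  for (sec in intersect(names(cfg), names(.schema))) {
    bad <- setdiff(names(cfg[[sec]]), .schema[[sec]])
    .chk(length(bad) == 0, "schema error at ", sec, ": unknown key(s): ",
         paste(paste0(sec, "/", bad), collapse = ", "))
  }
  for (sec in c("tumor_transport", "systemic_pk", "geometry"))
    .chk(sec %in% names(cfg), "schema error: missing section ", sec)
  ttc <- cfg$tumor_transport
  .chk(!is.null(ttc$TT_s), "schema error: tumor_transport/TT_s is required")
  .chk(!is.null(ttc$PS_per_s), "schema error: tumor_transport/PS_per_s is required")
  sd_tt <- list(v_p = ttc$v_p_sd, v_e_av = ttc$v_e_av_sd, TT = ttc$TT_sd_s,
                PS = ttc$PS_sd_per_s)
  sd_tt <- sd_tt[!vapply(sd_tt, is.null, logical(1))]
  tt <- tumor_transport(v_p = ttc$v_p, v_v = ttc$v_v, v_e = ttc$v_e,
                        k_av = ttc$k_av, v_e_av = ttc$v_e_av,
                        PS = ttc$PS_per_s, TT = ttc$TT_s,
                        Hct_mv = if (is.null(ttc$Hct_mv)) 0.19 else ttc$Hct_mv,
                        sd = sd_tt)
  pkc <- cfg$systemic_pk
  sd_pk <- list(V_D = pkc$V_D_sd_mL, V_p_S = pkc$V_p_S_sd_mL,
                k_p = pkc$k_p_sd_per_s, k_t = pkc$k_t_sd_per_s,
                k_e = pkc$k_e_sd_per_s)
  sd_pk <- sd_pk[!vapply(sd_pk, is.null, logical(1))]
  pk <- systemic_pk(V_D = pkc$V_D_mL, V_p_S = pkc$V_p_S_mL,
                    k_p = pkc$k_p_per_s, k_t = pkc$k_t_per_s,
                    k_e = pkc$k_e_per_s, sd = sd_pk)
  sd_geo <- if (is.null(cfg$geometry$VT_sd_mL)) list() else
    list(VT = cfg$geometry$VT_sd_mL)
  geo <- tumor_geometry(cfg$geometry$VT_mL, v_p = tt$v_p, sd = sd_geo)
  dose <- if (!is.null(cfg$dose))
    dose_spec(cfg$dose$ID, cfg$dose$form) else NULL
  bundle <- validate_params(tt, pk, geo, dose, F_p = ttc$F_p_per_s)
  if (!is.null(ttc$EF))
    # printed EF values come from unrounded inputs; allow ~0.01 slack
    .chk(abs(bundle$EF - ttc$EF) < 0.015,
         sprintf("schema error: EF %.3g inconsistent with derived %.3g",
                 ttc$EF, bundle$EF))
  bundle
}

#' Write a parameter bundle back to a JSON config
#'
#' @param params an `"ivdds_params"` bundle.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  .chk(inherits(params, "ivdds_params"), "params must be a validated bundle")
  tt <- params$tumor; pk <- params$pk
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  cfg <- list(
    tumor_transport = drop_null(list(
      v_p = tt$v_p, v_p_sd = tt$sd$v_p, v_v = tt$v_v, v_e = tt$v_e,
      k_av = tt$k_av, v_e_av = tt$v_e_av, v_e_av_sd = tt$sd$v_e_av,
      TT_s = tt$TT, TT_sd_s = tt$sd$TT, PS_per_s = tt$PS,
      PS_sd_per_s = tt$sd$PS, Hct_mv = tt$Hct_mv,
      F_p_per_s = params$F_p)),
    systemic_pk = drop_null(list(
      V_D_mL = pk$V_D, V_D_sd_mL = pk$sd$V_D, V_p_S_mL = pk$V_p_S,
      V_p_S_sd_mL = pk$sd$V_p_S, k_p_per_s = pk$k_p,
      k_p_sd_per_s = pk$sd$k_p, k_t_per_s = pk$k_t,
      k_t_sd_per_s = pk$sd$k_t, k_e_per_s = pk$k_e,
      k_e_sd_per_s = pk$sd$k_e)),
    geometry = drop_null(list(VT_mL = params$geometry$VT,
                              VT_sd_mL = params$geometry$sd$VT))
  )
  if (!is.null(params$dose))
    cfg$dose <- list(ID = params$dose$ID, form = params$dose$form)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged in-vivo parameter fixture
#'
#' Loads the packaged config holding the measured tumor transport and
#' pharmacokinetic parameter set (with standard deviations) plus the model
#' geometry assumptions (`V_p_S`, `VT`; chosen so the tumor:systemic
#' plasma ratio is 1:700).
#'
#' @param dose optional [dose_spec()] to attach.
#' @return an `"ivdds_params"` bundle.
#' @export
invivo_params <- function(dose = NULL) {
  path <- system.file("extdata", "invivo_params.json", package = "ivdds",
                      mustWork = TRUE)
  bundle <- load_config(path)
  if (!is.null(bundle$dose) && !is.null(dose)) bundle$dose <- dose
  if (is.null(bundle$dose)) bundle$dose <- dose
  bundle
}

#' Read a time-series CSV
#'
#' Enforces the package CSV dialect: a header with unit-suffixed column
#' names, a strictly increasing time column (suffix `_s`), and the
#' expected value columns.
#'
#' @param path CSV path.
#' @param columns required column names (the first must be the time
#'   column, e.g. `"time_s"`).
#' @return data.frame with the requested columns.
#' @export
read_timeseries_csv <- function(path, columns) {
  .chk(file.exists(path), "file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(columns, names(df))
  .chk(length(missing) == 0, "parse error: missing column(s): ",
       paste(missing, collapse = ", "))
  tc <- columns[1]
  .chk(grepl("_s$", tc), "parse error: time column '", tc,
       "' lacks the _s unit suffix")
  tv <- df[[tc]]
  bad <- which(diff(tv) <= 0)
  .chk(length(bad) == 0,
       "parse error: time not strictly increasing at data line(s) ",
       paste(bad + 1L, collapse = ", "))
  df[columns]
}

#' Write a time-series CSV
#'
#' Floats are serialized with 17 significant digits so that write/read
#' round trips are exact.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
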