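FOREARM_CONDITIONS <- c("pronation", "neutral", "supination")
WRIST_CONDITIONS <- c("extension", "neutral", "flexion")

#' Grip-strength literature table
#'
#' Twelve published studies reporting maximal grip strength as a percentage
#' of the neutral-posture maximum voluntary contraction (MVC), for each
#' combination of forearm posture (pronation / neutral / supination) and
#' wrist posture (extension / neutral / flexion). Missing cells mean the
#' study did not report that condition. These percentages quantify how much
#' power grasp a posture physiologically permits (tenodesis and
#' length-tension effects of the extrinsic finger muscles), and are the
#' basis of the feasible activation limits for combined-action targets.
#' Ulnar/radial deviation is purposefully excluded.
#'
#' @param path CSV file to read; defaults to the table shipped with the
#'   package (columns: `study`, `n`, nine `forearm_wrist` condition columns
#'   in percent, `note`).
#' @return A data frame of class `grip_table`.
#' @export
grip_strength_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "grip_strength_table.csv",
                        package = "tactomyo")
  tab <- read.csv(path, check.names = FALSE)
  need <- c("study", "n", condition_keys())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_format("grip table is missing columns: ", paste(miss, collapse = ", "))
  vals <- as.matrix(tab[, condition_keys()])
  if (any(!is.na(vals) & (vals <= 0 | vals > 200)))
    stop_validation("grip-strength percentages must lie in (0, 200]")
  class(tab) <- c("grip_table", "data.frame")
  tab
}

condition_keys <- function() {
  as.vector(outer(FOREARM_CONDITIONS, WRIST_CONDITIONS, paste, sep = "_"))
}

# round half away from zero (reporting convention for percentages)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Mean grip strength for one posture condition
#'
#' Arithmetic mean over the studies that report the condition (missing
#' cells excluded), i.e. an average over methods. Returned both unrounded
#' (used downstream to derive limits) and rounded to the nearest integer
#' (half away from zero; the reporting convention).
#'
#' @param table a [grip_strength_table()].
#' @param forearm `"pronation"`, `"neutral"` or `"supination"`.
#' @param wrist `"extension"`, `"neutral"` or `"flexion"`.
#' @return A list with `value` (unrounded percent), `rounded`, `n_studies`.
#' @examples
#' tab <- grip_strength_table()
#' condition_mean(tab, "neutral", "flexion")$rounded   # 66
#' condition_mean(tab, "pronation", "neutral")$rounded # 87
#' @export
condition_mean <- function(table, forearm, wrist) {
  forearm <- match.arg(forearm, FOREARM_CONDITIONS)
  wrist <- match.arg(wrist, WRIST_CONDITIONS)
  key <- paste(forearm, wrist, sep = "_")
  v <- table[[key]]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop_validation("no study reports the condition ", key)
  list(value = mean(v), rounded = as.integer(round_half_up(mean(v))),
       n_studies = length(v))
}

#' Full mean row over all nine conditions
#'
#' @param table a [grip_strength_table()].
#' @param rounded return rounded integers (default) or unrounded means.
#' @return Named numeric vector over the nine `forearm_wrist` conditions.
#' @export
grip_mean_row <- function(table, rounded = TRUE) {
  out <- vapply(condition_keys(), function(key) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    cm <- condition_mean(table, parts[1], parts[2])
    if (rounded) as.numeric(cm$rounded) else cm$value
  }, numeric(1))
  out
}

#' Derive a feasible activation level from a grip-strength percentage
#'
#' `level = (mean_pct / 100) * factor`, clamped to `[0, 1]`. The default
#' alleviating factor of 0.8 leaves a safety margin below the physiological
#' extreme so that targets stay comfortable and attainable.
#'
#' @param mean_pct grip-strength percentage (e.g. from [condition_mean()]).
#' @param factor alleviating factor in `(0, 1]`.
#' @return Activation level in `[0, 1]`.
#' @examples
#' derive_limit(100, 0.8)  # 0.8
#' derive_limit(66, 0.8)   # 0.528
#' @export
derive_limit <- function(mean_pct, factor = 0.8) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop_validation("alleviating factor must lie in (0, 1]")
  if (!is.numeric(mean_pct) || any(mean_pct <= 0))
    stop_validation("mean_pct must be positive")
  clamp01(mean_pct / 100 * factor)
}

#' Feasible activation limits for single and combined actions
#'
#' Maps each action combination to per-activation maximal feasible levels.
#' Power-grasp levels are derived from the grip-strength table: the mean of
#' the posture condition matching the combined wrist/forearm action,
#' alleviated once by `factor`. Wrist-only levels (no literature data
#' exists for wrist DoFs without grasp) are configured, not table-derived,
#' defaulting to `wrist_level` per involved activation.
#'
#' @param table a [grip_strength_table()].
#' @param factor alleviating factor (default 0.8).
#' @param wrist_level configured maximal level for non-power activations.
#' @return A list keyed by combination name; each element has `levels`
#'   (named activation levels) and `provenance` (`"table-derived"` or
#'   `"configured"` per activation).
#' @export
activation_limits <- function(table = grip_strength_table(), factor = 0.8,
                              wrist_level = 0.8) {
  power_for <- function(forearm, wrist)
    derive_limit(condition_mean(table, forearm, wrist)$value, factor)
  wrist_cond <- c(power = "neutral", flexion = "flexion",
                  extension = "extension")
  forearm_cond <- c(power = "neutral", pronation = "pronation",
                    supination = "supination")
  lim <- list()
  add <- function(name, levels, prov) {
    lim[[name]] <<- list(levels = levels, provenance = prov)
  }
  # singles
  add("power", c(power = power_for("neutral", "neutral")),
      c(power = "table-derived"))
  for (a in setdiff(MOTOR_ACTIONS, "power"))
    add(a, setNames(wrist_level, a), setNames("configured", a))
  # wrist-only pairs (non-antagonist)
  for (w in c("flexion", "extension")) for (f in c("pronation", "supination"))
    add(paste(w, f, sep = "+"),
        setNames(c(wrist_level, wrist_level), c(w, f)),
        setNames(c("configured", "configured"), c(w, f)))
  # power pairs: grip limit from the matching posture condition
  for (a in setdiff(MOTOR_ACTIONS, "power")) {
    fe <- if (a %in% names(forearm_cond)) forearm_cond[[a]] else "neutral"
    wr <- if (a %in% names(wrist_cond)) wrist_cond[[a]] else "neutral"
    add(paste("power", a, sep = "+"),
        setNames(c(power_for(fe, wr), wrist_level), c("power", a)),
        setNames(c("table-derived", "configured"), c("power", a)))
  }
  structure(lim, factor = factor, class = "activation_limits")
}

#' A TAC task target
#'
#' @param name task identifier.
#' @param activations named levels in `[0, 1]` over involved activations;
#'   uninvolved motor activations are filled with zero.
#' @param group `"single"`, `"combined-no-power"` or
#'   `"combined-with-power"`.
#' @return An object of class `target_spec` with full per-activation levels
#'   over all motor actions.
#' @export
target_spec <- function(name, activations, group) {
  group <- match.arg(group,
                     c("single", "combined-no-power", "combined-with-power"))
  if (length(activations) == 0L || all(activations == 0))
    stop_validation("target '", name, "' has no nonzero activation")
  bad <- setdiff(names(activations), MOTOR_ACTIONS)
  if (length(bad))
    stop_validation("unknown activation(s) in target '", name, "': ",
                    paste(bad, collapse = ", "))
  if (any(activations < 0 | activations > 1))
    stop_validation("target '", name, "' has levels outside [0, 1]")
  levels <- setNames(numeric(length(MOTOR_ACTIONS)), MOTOR_ACTIONS)
  levels[names(activations)] <- as.numeric(activations)
  structure(list(name = name, levels = levels, group = group),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  inv <- x$levels[x$levels > 0]
  cat(sprintf("<target_spec> %s [%s]: %s\n", x$name, x$group,
              paste(sprintf("%s=%.3f", names(inv), inv), collapse = ", ")))
  invisible(x)
}

#' Default task configuration
#'
#' The 13-task set: 5 single actions, 4 combined wrist actions without the
#' power grasp, and 4 combinations including the power grasp. Single and
#' wrist-only levels default to 0.8 (the alleviating factor applied to full
#' activation; wrist-only values are configured, not literature-derived).
#' Power levels come from the grip-strength limits of the matching posture.
#'
#' @param limits an [activation_limits()] object.
#' @param single_level level used for single non-power actions and for the
#'   non-power member of combinations.
#' @return A list of task definitions consumable by [build_task_set()].
#' @export
default_task_config <- function(limits = activation_limits(),
                                single_level = 0.8) {
  pw <- function(combo) limits[[combo]]$levels[["power"]]
  tasks <- list(
    list(name = "power", activations = c(power = pw("power")),
         group = "single"),
    list(name = "flexion", activations = c(flexion = single_level),
         group = "single"),
    list(name = "extension", activations = c(extension = single_level),
         group = "single"),
    list(name = "pronation", activations = c(pronation = single_level),
         group = "single"),
    list(name = "supination", activations = c(supination = single_level),
         group = "single"))
  for (w in c("flexion", "extension")) for (f in c("pronation", "supination"))
    tasks[[length(tasks) + 1L]] <-
      list(name = paste(w, f, sep = "+"),
           activations = setNames(c(single_level, single_level), c(w, f)),
           group = "combined-no-power")
  for (a in setdiff(MOTOR_ACTIONS, "power"))
    tasks[[length(tasks) + 1L]] <-
      list(name = paste("power", a, sep = "+"),
           activations = setNames(c(pw(paste("power", a, sep = "+")),
                                    single_level), c("power", a)),
           group = "combined-with-power")
  tasks
}

#' Build the ordered, method-alternating task set
#'
#' Validates every requested level against the activation limits, then
#' produces the TAC trial plan: each task once per method, in a randomized
#' order that is deterministic under the seed, while maintaining the
#' alternation between methods.
#'
#' @param limits an [activation_limits()] object.
#' @param config task list as from [default_task_config()].
#' @param methods method tags to alternate between.
#' @param seed integer seed for the randomized ordering.
#' @param start_method method of the first trial (default the first of
#'   `methods`).
#' @return A list of trial entries, each with `target` (a [target_spec()])
#'   and `method`; attribute `n_tasks` gives tasks per method.
#' @export
build_task_set <- function(limits = activation_limits(),
                           config = default_task_config(limits),
                           methods = c("raw", "roig"), seed = 1,
                           start_method = methods[1]) {
  targets <- lapply(config, function(tk) {
    tg <- target_spec(tk$name, tk$activations, tk$group)
    lv <- limits[[tk$name]]
    if (!is.null(lv)) {
      for (a in names(lv$levels)) {
        if (tg$levels[[a]] > lv$levels[[a]] + 1e-12)
          stop_validation("task '", tk$name, "' requests ", a, " = ",
                          tg$levels[[a]], " above its limit ",
                          signif(lv$levels[[a]], 6))
      }
    }
    tg
  })
  start_method <- match.arg(start_method, methods)
  ord <- order(match(methods, methods) != match(start_method, methods))
  methods <- methods[ord]
  n <- length(targets)
  set.seed(as.integer(seed))
  plan <- list()
  orders <- lapply(methods, function(m) sample.int(n))
  for (i in seq_len(n)) {
    for (j in seq_along(methods)) {
      plan[[length(plan) + 1L]] <-
        list(target = targets[[orders[[j]][i]]], method = methods[j])
    }
  }
  structure(plan, n_tasks = n, methods = methods)
}
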