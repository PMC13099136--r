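## Canonical label sets shared across the package.

#' Task epoch labels
#'
#' The nine within-trial epochs, in order: `ITI-a`, `Light`, `Poke`,
#' `Odor`, `Unpoke`, `Choice`, `Outcome`, `postOut`, `ITI-b`.
#' @export
EPOCHS <- c("ITI-a", "Light", "Poke", "Odor", "Unpoke", "Choice",
            "Outcome", "postOut", "ITI-b")

#' Sequence and position labels
#' @rdname EPOCHS
#' @export
SEQUENCES <- c("S1", "S2")

#' @rdname EPOCHS
#' @export
POSITIONS <- c("P1", "P2", "P3", "P4")

# Event columns of the trial table, in required temporal order.
TRIAL_EVENT_COLS <- c("light_on", "poke_in", "odor_on", "poke_out",
                      "well_entry", "reward_time")

# Trial-tensor block layout: trials grouped position-major, sequence within
# position, so blocks 1..8 = P1(S1), P1(S2), P2(S1), ..., P4(S2); rewarded
# trials therefore occupy blocks 1-2 and 7-8 (trials 1-80 and 241-320 of a
# complete 40-repeat session).
TENSOR_BLOCK_ORDER <- data.frame(
  position = rep(POSITIONS, each = 2L),
  sequence = rep(SEQUENCES, 4L))
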