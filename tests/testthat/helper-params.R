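# shared fixtures: packaged parameter sets (b calibrated once per session)
p_ref <- edema_params()
po_ref <- edema_params("table1_2021")

# closed-form eye-opening swelling written out independently of the
# package's evaluation path, for cross-checking
eye_open_oracle <- function(di, dc, p) {
  (p$Bnap + p$Bdiff) * exp(-(di * p$kD + dc * p$kcD)) +
    (p$L0 + p$Ldiff) * (di^(-p$b) - p$DN^(-p$b))
}
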