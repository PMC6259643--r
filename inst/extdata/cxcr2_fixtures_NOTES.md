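# Transcription notes for the CXCR2 activity fixtures

`cxcr2_activity.csv` transcribes the compound id, IC50, unit and printed
pIC50 columns of the published activity tables of the CXCR2 antagonist data
set (126 of 130 compounds; column `source_table` records which table a row
came from). `cxcr2_test_predictions.csv` transcribes the 16 printed
prediction-set rows (experimental pIC50 and the predicted/residual pairs for
the PLS, GA-PLS and stepwise-MLR models).

Known transcription caveats, all decided before any numeric use:

- The fourth activity table of the source (ids would be 1a-1f / 10a-10f) is
  not machine-recoverable: id, IC50 and pIC50 cells are merged in the
  available text (e.g. "1a10a ... 8.529.00"). It is excluded; hence 126
  rows, not 130.
- The second table prints its IC50 unit as nM, but rows 26-46 are only
  self-consistent with the printed pIC50 when read as micromolar, while rows
  47-58 are consistent as nanomolar. The unit column keeps the printed "nM";
  self-consistency of each row is decided computationally
  (round(-log10(IC50 in M), 2) == printed pIC50).
- Several rows are not self-consistent at 2 decimal places, e.g. row 1
  (0.07 uM -> 7.15 computed vs 7.14 printed) and row 75 (39 nM -> 7.41
  computed vs 7.49 printed). Such rows are never used as numeric conversion
  targets; `cxcr2_activities()` flags them.
- In the prediction table, residuals are printed as predicted minus
  experimental; a few rows differ from that difference by 0.01 (rounding of
  the unprinted full-precision predictions). Row 47 is internally
  inconsistent as printed: all three methods' residuals imply an
  experimental value of 6.18, not the printed 6.14 (deviation 0.03-0.04).
  It is transcribed as printed and excluded from residual-convention checks.
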