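# Minimal end-to-end pipeline configuration: a 4-subject, 2-trial synthetic
# cohort evaluated with the DFT + SVM method only.
seed: 2
out_dir: skillflow_smoke
cohort:
  n_subjects: 4
  trials_per_subject: 2
  task_names: toy_task
  n_frames: 40
window:
  size: 30
  step: 9
class_mode: two_class
methods: dft
heads: svm
n_runs: 1
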