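backprojection: mossy_soma
g_nmda_p: 0.001
g_p_ms: 0.0001
g_p_di: 0.0
g_c: 2.1
conductances:
  g_g_ms: 0.001
  g_g_di: 0.0005
  g_di_g: 0.0005
  g_di_ms: 0.001
  g_ms_g: 0.0002
  g_ms_di: 0.0002
  g_ampa_p: 0.0005
  g_p_i: 0.0005
  g_p_o: 0.004
  g_i_p: 0.001
  g_o_p: 0.001
  g_i_o: 0.0005
  g_o_i: 0.0005
include_io: no
i_ext: 0.35
i_ext_cells: []
cell_overrides: []
syn_gain: 200.0
duration_s: 10.0
step_ms: 0.01
record_dt_ms: 0.05
v_thresh: -20.0
mg: 1.0
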