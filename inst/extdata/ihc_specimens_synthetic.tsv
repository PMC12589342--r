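specimen_id	percent_positive	intensity
P1	5	none
P2	30	moderate
P3	15	weak
P4	60	strong
P5	55	moderate
P6	80	strong
P7	40	strong
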