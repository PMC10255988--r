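[{"chest_width":30.6,"hip_width":29,"chest_height":67.5,"hip_height":68.1,"body_length":97.7,"identity":0,"weight":89},{"chest_width":32.1,"hip_width":30.1,"chest_height":66.4,"hip_height":68.3,"body_length":95.4,"identity":1,"weight":87.5},{"chest_width":30.3,"hip_width":25.5,"chest_height":56.6,"hip_height":56.9,"body_length":82.8,"identity":2,"weight":75},{"chest_width":27.7,"hip_width":28.1,"chest_height":57.5,"hip_height":57.9,"body_length":86.8,"identity":3,"weight":76.5},{"chest_width":29.6,"hip_width":26,"chest_height":57.8,"hip_height":58.9,"body_length":86.6,"identity":4,"weight":77.5},{"chest_width":31.5,"hip_width":28.5,"chest_height":63.6,"hip_height":65.6,"body_length":96.7,"identity":5,"weight":88},{"chest_width":30.56,"hip_width":31.28,"chest_height":60.9,"hip_height":62.7,"body_length":90.6,"identity":6,"weight":89.5},{"chest_width":25.9,"hip_width":23.8,"chest_height":53.2,"hip_height":55.3,"body_length":85.9,"identity":7,"weight":63.5},{"chest_width":27.6,"hip_width":23.6,"chest_height":54.4,"hip_height":55.7,"body_length":89.2,"identity":8,"weight":69},{"chest_width":25.9,"hip_width":28,"chest_height":52.1,"hip_height":56.2,"body_length":77.4,"identity":9,"weight":60.5}]
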