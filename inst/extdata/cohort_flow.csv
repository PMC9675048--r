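metric,numerator,denominator
sms_response,1342,6553
consumption_measured,2868,6553
telephone_response,1980,3302
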